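# Independent graph oracles via the system python + networkx installation.

nx_run <- function(code) {
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE,
                 stderr = FALSE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("python oracle failed")
  out
}

# planarity of an undirected graph with integer nodes 0..n-1
nx_is_planar <- function(n, u, v) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write.table(cbind(u, v), tf, row.names = FALSE, col.names = FALSE)
  code <- sprintf("
import networkx as nx
G = nx.Graph(); G.add_nodes_from(range(%d))
for line in open(r'%s'):
    a, b = line.split(); G.add_edge(int(a), int(b))
print(int(nx.check_planarity(G)[0]))", n, tf)
  as.integer(nx_run(code)) == 1L
}

# independently coded greedy PMFG: visits candidate rows in the given order,
# keeps an edge iff networkx still certifies planarity
nx_greedy_pmfg <- function(n, u, v) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write.table(cbind(u, v), tf, row.names = FALSE, col.names = FALSE)
  code <- sprintf("
import networkx as nx
edges = [tuple(map(int, l.split())) for l in open(r'%s')]
G = nx.Graph(); G.add_nodes_from(range(%d))
target = 3 * (%d - 2)
kept = []
for a, b in edges:
    if G.number_of_edges() >= target:
        kept.append(0); continue
    G.add_edge(a, b)
    if nx.check_planarity(G)[0]:
        kept.append(1)
    else:
        G.remove_edge(a, b)
        kept.append(0)
print('\\n'.join(map(str, kept)))", tf, n, n)
  as.integer(nx_run(code)) == 1L
}

# brute-force one-sided hypergeometric upper tail from the pmf definition
enum_fisher_p <- function(overlap, n_query, n_target, n_universe) {
  ks <- overlap:min(n_query, n_target)
  sum(choose(n_target, ks) * choose(n_universe - n_target, n_query - ks)) /
    choose(n_universe, n_query)
}

# brute-force Benjamini-Hochberg adjusted values
brute_bh <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    min(1, min(vapply(which(p >= p[i]), function(j) {
      n * p[j] / sum(p <= p[j])
    }, numeric(1))))
  }, numeric(1))
}
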