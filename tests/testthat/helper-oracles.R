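# Independent brute-force oracles, written directly against the edge matrix
# and node-age vector so they share no code with the implementation.

bf_bray <- function(x, y) {
  taxa <- union(names(x), names(y))
  xv <- yv <- numeric(length(taxa))
  names(xv) <- names(yv) <- taxa
  xv[names(x)] <- x
  yv[names(y)] <- y
  num <- 0
  den <- 0
  for (t in taxa) {
    num <- num + abs(xv[[t]] - yv[[t]])
    den <- den + xv[[t]] + yv[[t]]
  }
  num / den
}

bf_simpson <- function(comm) {
  comm <- comm[comm > 0]
  p <- comm / sum(comm)
  acc <- 0
  for (i in seq_along(p)) acc <- acc + p[[i]]^2
  1 - acc
}

bf_parent <- function(phy) {
  p <- rep(NA_integer_, length(phy$tip.label) + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) p[phy$edge[e, 2]] <- phy$edge[e, 1]
  p
}

bf_root_path <- function(phy, node) {
  par <- bf_parent(phy)
  out <- integer(0)
  v <- node
  while (!is.na(v)) {
    out <- c(out, v)
    v <- par[v]
  }
  out
}

# PD: enumerate the union of nodes on all tip-to-root paths, sum the branch
# above each non-root member.
bf_pd <- function(dt, taxa) {
  phy <- dt$phy
  par <- bf_parent(phy)
  nodes <- integer(0)
  for (t in taxa)
    nodes <- union(nodes, bf_root_path(phy, match(t, phy$tip.label)))
  total <- 0
  for (v in nodes)
    if (!is.na(par[v])) total <- total + dt$ages[par[v]] - dt$ages[v]
  total
}

bf_patristic <- function(dt, a, b) {
  phy <- dt$phy
  pa <- bf_root_path(phy, match(a, phy$tip.label))
  pb <- bf_root_path(phy, match(b, phy$tip.label))
  mrca <- pa[pa %in% pb][1]
  da <- 0
  v <- match(a, phy$tip.label)
  par <- bf_parent(phy)
  while (v != mrca) {
    da <- da + dt$ages[par[v]] - dt$ages[v]
    v <- par[v]
  }
  db <- 0
  v <- match(b, phy$tip.label)
  while (v != mrca) {
    db <- db + dt$ages[par[v]] - dt$ages[v]
    v <- par[v]
  }
  da + db
}

bf_rao <- function(dt, species, areas) {
  ab <- tapply(areas, species, sum)
  p <- as.numeric(ab) / sum(ab)
  nm <- names(ab)
  acc <- 0
  for (i in seq_along(nm))
    for (j in seq_along(nm))
      if (i != j)
        acc <- acc + bf_patristic(dt, nm[i], nm[j]) * p[i] * p[j]
  acc
}

# star tree: n tips all attached directly to a root of age r
star_tree <- function(n, r, tips = paste0("t", seq_len(n))) {
  phy <- structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                        tip.label = tips, node.label = "root", Nnode = 1L),
                   class = "phylo", order = "cladewise")
  dated_tree(phy, ages = c(rep(0, n), r))
}

random_community <- function(n, taxa = sprintf("g%02d", seq_len(n))) {
  stats::setNames(stats::runif(n, 0.1, 100), sample(taxa))
}

fixture_tree <- function() {
  bladj_date(parse_newick("((A,B)ab,C)root;"), c(root = 10, ab = 5))
}

write_toy_panel <- function(path, rows) {
  utils::write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

toy_panel_df <- function() {
  data.frame(
    region = c("north", "north", "north", "south", "south", "south"),
    year = 1970L,
    item = c("wheat", "maize", "barley", "wheat", "maize", "maize"),
    element = c(rep("Area harvested", 5), "Production"),
    value = c(100, 50, 10, 80, 40, 999),
    stringsAsFactors = FALSE)
}
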