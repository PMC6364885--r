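#' Dated crop phylogeny
#'
#' A `dated_tree` couples a rooted topology (an [ape] `phylo`, polytomies
#' permitted) with node ages in millions of years (My): tips have age 0,
#' internal nodes either carry a calibrated/interpolated age or `NA` when not
#' yet dated. Branch lengths are derived, length(child) = age(parent) -
#' age(child), and are only defined once every node is dated (see
#' [bladj_date()]).
#'
#' @param phy an `ape::phylo`.
#' @param ages numeric vector of node ages indexed by ape node number
#'   (tips `1..Ntip`, then internals); tips must be 0. Defaults to undated
#'   (internal ages `NA`).
#' @return an object of class `dated_tree`.
#' @export
dated_tree <- function(phy, ages = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("parse error: duplicate tip labels")
  n <- length(phy$tip.label)
  nn <- phy$Nnode
  if (is.null(ages)) ages <- c(rep(0, n), rep(NA_real_, nn))
  stopifnot(length(ages) == n + nn)
  if (any(ages[seq_len(n)] != 0))
    stop("tip ages must be 0")
  dt <- structure(list(phy = phy, ages = as.numeric(ages)),
                  class = "dated_tree")
  if (is_dated(dt)) dt <- derive_branch_lengths(dt)
  dt
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("dated_tree:", length(x$phy$tip.label), "tips,", x$phy$Nnode,
      "internal nodes,",
      if (is_dated(x)) sprintf("dated (root age %g My)", root_age(x))
      else "undated", "\n")
  invisible(x)
}

#' Is every node of a tree dated?
#' @param dt a `dated_tree`.
#' @return logical.
#' @export
is_dated <- function(dt) !anyNA(dt$ages)

root_node <- function(phy) {
  setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
}

root_age <- function(dt) dt$ages[root_node(dt$phy)]

#' All node labels, tips first
#' @param dt a `dated_tree`.
#' @return character vector of length Ntip + Nnode; unlabeled internal nodes
#'   are `NA`.
#' @export
node_labels <- function(dt) {
  phy <- dt$phy
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep(NA_character_, phy$Nnode)
  lab[!nzchar(lab)] <- NA_character_
  c(phy$tip.label, lab)
}

parent_vec <- function(phy) {
  p <- rep(NA_integer_, length(phy$tip.label) + phy$Nnode)
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

children_list <- function(phy) {
  split(phy$edge[, 2], factor(phy$edge[, 1],
                              levels = seq_len(length(phy$tip.label) +
                                                 phy$Nnode)))
}

derive_branch_lengths <- function(dt) {
  phy <- dt$phy
  phy$edge.length <- dt$ages[phy$edge[, 1]] - dt$ages[phy$edge[, 2]]
  dt$phy <- phy
  dt
}

#' Read a newick tree (undated)
#'
#' Topology, tip labels and internal labels are preserved exactly, including
#' polytomies and pass-through (single-child) nodes carrying calibration
#' labels; branch lengths in the file are ignored (ages come from a
#' calibration table via [bladj_date()]). The reader is self-contained
#' because trees with retained degree-2 nodes must round-trip losslessly.
#'
#' @param path path to a newick file.
#' @return an undated `dated_tree`.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Parse a newick string into an undated tree
#' @param text a newick string (single tree, terminated by `;`).
#' @return an undated `dated_tree`.
#' @export
parse_newick <- function(text) {
  s <- gsub("[ \t\r\n]", "", text)
  if (!grepl(";", s, fixed = TRUE)) stop("parse error: missing ';'")
  s <- sub(";.*$", "", s)
  n_char <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  pos <- 1L
  parent <- integer(0)
  label <- character(0)
  tip <- logical(0)
  peek <- function() if (pos <= n_char) chars[pos] else ""
  read_label <- function() {
    start <- pos
    while (pos <= n_char && !chars[pos] %in% c("(", ")", ",", ":"))
      pos <<- pos + 1L
    lab <- substr(s, start, pos - 1L)
    if (peek() == ":") {  # branch length present: skip it
      pos <<- pos + 1L
      while (pos <= n_char && !chars[pos] %in% c("(", ")", ","))
        pos <<- pos + 1L
    }
    lab
  }
  parse_subtree <- function(par) {
    id <- length(parent) + 1L
    parent[id] <<- par
    label[id] <<- ""
    tip[id] <<- TRUE
    if (peek() == "(") {
      tip[id] <<- FALSE
      pos <<- pos + 1L
      repeat {
        parse_subtree(id)
        if (peek() == ",") {
          pos <<- pos + 1L
          next
        }
        if (peek() == ")") {
          pos <<- pos + 1L
          break
        }
        stop("parse error: unbalanced parentheses")
      }
      label[id] <<- read_label()
    } else {
      label[id] <<- read_label()
      if (!nzchar(label[id])) stop("parse error: empty tip label")
    }
    id
  }
  parse_subtree(0L)
  if (pos <= n_char) stop("parse error: unbalanced parentheses")
  if (!any(!tip)) stop("parse error: no internal node")
  tip_ids <- which(tip)
  int_ids <- which(!tip)  # creation order is preorder; root comes first
  n_tip <- length(tip_ids)
  new_id <- integer(length(parent))
  new_id[tip_ids] <- seq_len(n_tip)
  new_id[int_ids] <- n_tip + seq_along(int_ids)
  kids <- which(parent > 0L)
  edge <- cbind(new_id[parent[kids]], new_id[kids])
  phy <- structure(list(edge = edge,  # child creation order = preorder
                        tip.label = label[tip_ids],
                        node.label = label[int_ids],
                        Nnode = length(int_ids)),
                   class = "phylo", order = "cladewise")
  dated_tree(phy)
}

#' Write a tree as newick
#'
#' Dated trees are written with derived branch lengths; undated trees
#' topology-only. Supports polytomies and retained degree-2 nodes.
#'
#' @param dt a `dated_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dt, path) {
  writeLines(newick_string(dt), path)
  invisible(path)
}

#' Serialize a tree to a newick string
#' @param dt a `dated_tree`.
#' @return newick string (with branch lengths when dated).
#' @export
newick_string <- function(dt) {
  phy <- dt$phy
  lab <- node_labels(dt)
  lab[is.na(lab)] <- ""
  kids <- children_list(phy)
  dated <- is_dated(dt)
  par <- parent_vec(phy)
  fmt <- function(v) {
    inner <- if (v <= length(phy$tip.label)) lab[v]
    else paste0("(", paste(vapply(kids[[v]], fmt, ""), collapse = ","),
                ")", lab[v])
    if (dated && !is.na(par[v]))
      inner <- paste0(inner, ":",
                      format(dt$ages[par[v]] - dt$ages[v], trim = TRUE))
    inner
  }
  paste0(fmt(root_node(phy)), ";")
}

#' Read a node-ages calibration table
#'
#' Whitespace-delimited lines `node-label age` (the Phylocom "ages" dialect);
#' ages in My, all > 0.
#'
#' @param path path to the ages file.
#' @return named numeric vector: internal-node label -> age (My).
#' @export
read_ages <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("label", "age"))
  ages <- df$age
  names(ages) <- df$label
  if (any(ages <= 0)) stop("validation error: calibration ages must be > 0")
  ages
}

#' Write a node-ages table
#' @param ages named numeric vector (label -> age).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ages <- function(ages, path) {
  writeLines(paste(names(ages), format(ages, trim = TRUE)), path)
  invisible(path)
}

#' Prune a tree to a taxon set
#'
#' Returns the minimal subtree spanning `taxa` and the original root.
#' Degree-2 pass-through internal nodes are retained with their labels so
#' that calibration entries survive pruning; branch lengths through them sum
#' identically, so diversity metrics are unaffected.
#'
#' @param dt a `dated_tree`.
#' @param taxa tip labels to keep (at least one).
#' @return a `dated_tree` on the kept nodes (ages carried over).
#' @export
prune_to_taxa <- function(dt, taxa) {
  phy <- dt$phy
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, phy$tip.label)
  if (length(unknown))
    stop("lookup error: taxa not in tree: ", paste(unknown, collapse = ", "))
  if (!length(taxa)) stop("at least one taxon required")
  par <- parent_vec(phy)
  keep <- logical(length(par))
  for (tip in match(taxa, phy$tip.label)) {
    v <- tip
    while (!is.na(v) && !keep[v]) {
      keep[v] <- TRUE
      v <- par[v]
    }
  }
  old_ids <- which(keep)
  old_tips <- old_ids[old_ids <= length(phy$tip.label)]
  old_ints <- old_ids[old_ids > length(phy$tip.label)]
  # preserve preorder so the root keeps the first internal number
  old_ints <- old_ints[order(match(old_ints, c(root_node(phy),
                                               phy$edge[, 2])))]
  new_id <- integer(length(par))
  new_id[old_tips] <- seq_along(old_tips)
  new_id[old_ints] <- length(old_tips) + seq_along(old_ints)
  esel <- keep[phy$edge[, 2]]  # parent kept whenever child kept
  edge <- cbind(new_id[phy$edge[esel, 1]], new_id[phy$edge[esel, 2]])
  lab <- node_labels(dt)
  new_phy <- structure(list(edge = edge,
                            tip.label = phy$tip.label[old_tips],
                            node.label = {
                              l <- lab[old_ints]
                              l[is.na(l)] <- ""
                              l
                            },
                            Nnode = length(old_ints)),
                       class = "phylo", order = "cladewise")
  dated_tree(new_phy, ages = dt$ages[c(old_tips, old_ints)])
}

#' Date a tree by even node-age interpolation
#'
#' Assigns an age to every uncalibrated internal node by spacing it evenly
#' between its nearest calibrated ancestor and a calibrated (or tip)
#' descendant, in the manner of the branch-length-adjustment approach used
#' with supertree phylogenies. Proceeding root-to-tip, each undated node
#' anchors to the calibrated node or tip (age `t_D`, tips at 0) reachable
#' from it through undated nodes only, preferring the oldest such anchor,
#' then the longest undated chain, then the lexicographically smallest
#' label; with m undated nodes on the parent-to-anchor path the node
#' receives `t_P - (t_P - t_D) / (m + 1)`, which telescopes to even spacing
#' `t_A - k (t_A - t_D) / (m + 1)` along a chain of m nodes below a dated
#' ancestor. The procedure is deterministic and topology-determined, and
#' ages strictly decrease root-to-tip even where undated regions branch.
#'
#' @param dt an (at least partially) undated `dated_tree`.
#' @param ages named numeric calibration vector (internal-node label -> My);
#'   must include the root's label; every calibrated node must be older than
#'   all of its calibrated descendants.
#' @return a fully dated `dated_tree` with derived branch lengths; ages
#'   strictly decrease from root to tips.
#' @export
bladj_date <- function(dt, ages) {
  phy <- dt$phy
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  lab <- node_labels(dt)
  age <- c(rep(0, n_tip), rep(NA_real_, phy$Nnode))
  hit <- !is.na(lab) & lab %in% names(ages)
  hit[seq_len(n_tip)] <- FALSE
  age[hit] <- ages[lab[hit]]
  root <- root_node(phy)
  if (is.na(age[root]))
    stop("validation error: root node must be calibrated (labelled and ",
         "present in the ages table)")
  par <- parent_vec(phy)
  kids <- children_list(phy)
  # calibration consistency: every aged node older than aged descendants
  for (v in which(!is.na(age) & seq_len(n_all) > n_tip)) {
    u <- par[v]
    while (!is.na(u)) {
      if (!is.na(age[u]) && age[u] <= age[v])
        stop("calibration-conflict error: node '", lab[u],
             "' (", age[u], " My) is not older than its calibrated ",
             "descendant '", lab[v], "' (", age[v], " My)")
      u <- par[u]
    }
  }
  dated <- !is.na(age)
  # Top-down even interpolation. For each undated node (parents first) the
  # anchor is the calibrated node or tip reachable through undated nodes
  # only, preferring the oldest anchor (so the node stays older than every
  # calibrated descendant), then the longest undated chain, then the
  # lexicographically smallest label. If the path parent -> anchor carries m
  # undated nodes, the node (its first) gets t_P - (t_P - t_D) / (m + 1);
  # applied recursively this telescopes to even spacing along chains and
  # ages strictly decrease root-to-tip by construction.
  endpoint_key <- function(v) {
    if (!is.na(lab[v])) lab[v] else sprintf("~%08d", v)
  }
  preorder <- integer(0)
  stack <- root_node(phy)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    preorder <- c(preorder, v)
    stack <- c(stack, rev(kids[[v]]))
  }
  for (v in preorder) {
    if (dated[v]) next
    best <- NULL
    dfs <- list(list(node = v, m = 1L))
    while (length(dfs)) {
      top <- dfs[[length(dfs)]]
      dfs[[length(dfs)]] <- NULL
      for (ch in kids[[top$node]]) {
        if (dated[ch]) {
          cand <- list(d = ch, m = top$m, a = age[ch],
                       key = endpoint_key(ch))
          if (is.null(best) || cand$a > best$a ||
              (cand$a == best$a && cand$m > best$m) ||
              (cand$a == best$a && cand$m == best$m &&
                 cand$key < best$key))
            best <- cand
        } else {
          dfs[[length(dfs) + 1L]] <- list(node = ch, m = top$m + 1L)
        }
      }
    }
    t_p <- age[par[v]]
    age[v] <- t_p - (t_p - best$a) / (best$m + 1)
    dated[v] <- TRUE
  }
  bad <- age[phy$edge[, 1]] <= age[phy$edge[, 2]]
  if (any(bad))
    stop("calibration-conflict error: interpolated ages do not strictly ",
         "decrease along ", sum(bad), " edge(s)")
  dated_tree(phy, ages = age)
}

#' Total branch length spanned by a taxon set (Faith's PD support)
#'
#' Sum of the branch lengths of the minimal subtree connecting `taxa` to the
#' root (root path included), in My.
#'
#' @param dt a dated `dated_tree`.
#' @param taxa tip labels (at least one).
#' @return total branch length (My).
#' @export
total_branch_length <- function(dt, taxa) {
  if (!is_dated(dt)) stop("state error: tree is not dated")
  phy <- dt$phy
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, phy$tip.label)
  if (length(unknown))
    stop("lookup error: taxa not in tree: ", paste(unknown, collapse = ", "))
  par <- parent_vec(phy)
  keep <- logical(length(par))
  for (tip in match(taxa, phy$tip.label)) {
    v <- tip
    while (!is.na(v) && !keep[v]) {
      keep[v] <- TRUE
      v <- par[v]
    }
  }
  on <- which(keep & !is.na(par))  # every kept non-root node contributes
  sum(dt$ages[par[on]] - dt$ages[on])
}

#' Patristic distance between two tips
#'
#' Branch-length path distance; with tips at age 0 this equals twice the age
#' of the most recent common ancestor.
#'
#' @param dt a dated `dated_tree`.
#' @param a,b tip labels.
#' @return distance in My.
#' @export
patristic_distance <- function(dt, a, b) {
  if (!is_dated(dt)) stop("state error: tree is not dated")
  phy <- dt$phy
  ia <- match(a, phy$tip.label)
  ib <- match(b, phy$tip.label)
  if (is.na(ia) || is.na(ib))
    stop("lookup error: unknown tip ",
         paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  if (ia == ib) return(0)
  par <- parent_vec(phy)
  anc <- integer(0)
  v <- ia
  while (!is.na(v)) {
    anc <- c(anc, v)
    v <- par[v]
  }
  v <- ib
  while (!(v %in% anc)) v <- par[v]
  mrca <- v
  (dt$ages[mrca] - dt$ages[ia]) + (dt$ages[mrca] - dt$ages[ib])
}

#' Patristic distance matrix among a set of tips
#'
#' @param dt a dated `dated_tree`.
#' @param tips tip labels (default all).
#' @return symmetric numeric matrix (My) with zero diagonal.
#' @export
patristic_matrix <- function(dt, tips = dt$phy$tip.label) {
  if (!is_dated(dt)) stop("state error: tree is not dated")
  phy <- dt$phy
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx))
    stop("lookup error: unknown tip ", paste(tips[is.na(idx)], collapse = ", "))
  par <- parent_vec(phy)
  paths <- lapply(idx, function(tip) {
    v <- tip
    out <- integer(0)
    while (!is.na(v)) {
      out <- c(out, v)
      v <- par[v]
    }
    out
  })
  k <- length(idx)
  d <- matrix(0, k, k, dimnames = list(tips, tips))
  for (i in seq_len(k)) {
    pi_set <- paths[[i]]
    for (j in seq_len(k)) {
      if (j >= i) break
      mrca <- paths[[j]][match(TRUE, paths[[j]] %in% pi_set)]
      val <- 2 * dt$ages[mrca] - dt$ages[idx[i]] - dt$ages[idx[j]]
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Drop all internal node ages (keep topology and labels)
#' @param dt a `dated_tree`.
#' @return an undated `dated_tree`.
#' @export
undate <- function(dt) {
  phy <- dt$phy
  phy$edge.length <- NULL
  dated_tree(phy)
}
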