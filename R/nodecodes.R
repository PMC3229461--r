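# NodeCodes DAG labeling: every node receives the set of codes of the
# root-to-node paths from a virtual source, so descendant/ancestor tests
# reduce to code-prefix tests with no graph traversal at query time.

#' Construct a directed acyclic graph
#'
#' @param edges two-column data frame or matrix of (parent, child) node ids;
#'   may have zero rows.
#' @param nodes optional character vector of node ids (isolated nodes are
#'   only representable this way); defaults to the nodes appearing in
#'   `edges`.
#' @return an object of class `sb_dag` with elements `nodes` (sorted ids),
#'   `edges` (parent/child data frame) and `children` (adjacency list in
#'   lexicographic sibling order).  Construction fails on self-loops and
#'   cycles, naming one offending cycle.
#' @export
sb_dag <- function(edges, nodes = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  } else {
    names(edges)[1:2] <- c("parent", "child")
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
    edges <- edges[!duplicated(edges[c("parent", "child")]), , drop = FALSE]
  }
  if (any(edges$parent == edges$child)) {
    stop("cycle error: self-loop at node '",
         edges$parent[edges$parent == edges$child][1], "'", call. = FALSE)
  }
  nodes <- sort(unique(c(nodes, edges$parent, edges$child)))
  children <- split(edges$child, factor(edges$parent, levels = nodes))
  children <- lapply(children, sort)
  indeg <- table(factor(edges$child, levels = nodes))
  # Kahn's algorithm doubles as the cycle check
  indeg_v <- as.integer(indeg)
  names(indeg_v) <- nodes
  queue <- character(length(nodes))
  roots <- nodes[indeg_v == 0L]
  queue[seq_along(roots)] <- roots
  tail <- length(roots)
  head <- 1L
  seen <- 0L
  while (head <= tail) {
    u <- queue[[head]]; head <- head + 1L
    seen <- seen + 1L
    for (v in children[[u]]) {
      indeg_v[[v]] <- indeg_v[[v]] - 1L
      if (indeg_v[[v]] == 0L) {
        tail <- tail + 1L
        queue[[tail]] <- v
      }
    }
  }
  if (seen < length(nodes)) {
    cyc <- names(indeg_v)[indeg_v > 0L]
    stop("cycle error: cycle through node(s) ",
         paste(utils::head(cyc, 5), collapse = " -> "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, children = children),
            class = "sb_dag")
}

#' @export
print.sb_dag <- function(x, ...) {
  cat("<sb_dag> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Read a DAG from a child-parent edge-list TSV
#'
#' The file has a header row and columns `child` and `parent` (extra columns
#' are ignored); a row with an empty parent declares an isolated node.
#'
#' @param path TSV file path.
#' @return an [sb_dag()].
#' @export
read_dag_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("child", "parent") %in% names(df)))
  has_parent <- nzchar(df$parent)
  sb_dag(data.frame(parent = df$parent[has_parent],
                    child = df$child[has_parent],
                    stringsAsFactors = FALSE),
         nodes = unique(df$child))
}

#' Assign NodeCodes to every node of a DAG
#'
#' All roots (in-degree 0) are treated as children of a virtual source node
#' whose only code is the empty string.  Nodes are processed in FIFO
#' topological order — the code set of a node is complete before any of its
#' codes propagate — and within a node, children are ranked in lexicographic
#' sibling order: for each code `x` of the node, child number `i` (0-based)
#' receives the code `x.i`.  Codes are delimiter-separated integer
#' components, so the prefix relation is component-wise and unambiguous for
#' nodes with ten or more children.
#'
#' @param dag an [sb_dag()].
#' @param max_codes guard against path-count explosion on dense DAGs; an
#'   error is raised when the total number of codes would exceed it.
#' @return object of class `nodecodes_labeling` with elements `nc` (named
#'   list node -> character vector of codes), `all_codes` / `all_nodes`
#'   (flattened parallel vectors used for prefix scans) and `code_node`
#'   (environment mapping each code to its node).
#' @export
assign_nodecodes <- function(dag, max_codes = 1e7) {
  stopifnot(inherits(dag, "sb_dag"))
  nodes <- dag$nodes
  n <- length(nodes)
  nc <- vector("list", n)
  names(nc) <- nodes
  if (n == 0L) {
    return(structure(list(nc = nc, all_codes = character(),
                          all_nodes = character(),
                          code_node = new.env(parent = emptyenv()),
                          nodes = nodes),
                     class = "nodecodes_labeling"))
  }
  indeg <- integer(n)
  names(indeg) <- nodes
  tab <- table(dag$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  roots <- nodes[indeg == 0L]  # already in lexicographic order
  # virtual source: NC = { "" }; its children (the roots) get codes "0".."k"
  for (i in seq_along(roots)) nc[[roots[i]]] <- as.character(i - 1L)
  total <- length(roots)
  # FIFO topological propagation: a node's code set is complete before it
  # is dequeued and propagates
  queue <- character(n)
  queue[seq_along(roots)] <- roots
  tail <- length(roots)
  head <- 1L
  remaining <- indeg
  while (head <= tail) {
    u <- queue[[head]]; head <- head + 1L
    kids <- dag$children[[u]]
    if (length(kids)) {
      codes_u <- nc[[u]]
      for (i in seq_along(kids)) {
        v <- kids[[i]]
        new_codes <- paste0(codes_u, ".", i - 1L)
        nc[[v]] <- c(nc[[v]], new_codes)
        total <- total + length(new_codes)
        if (total > max_codes) {
          stop("code-set explosion: more than ", format(max_codes),
               " NodeCodes required; the DAG is too dense for path labeling",
               call. = FALSE)
        }
        remaining[[v]] <- remaining[[v]] - 1L
        if (remaining[[v]] == 0L) {
          tail <- tail + 1L
          queue[[tail]] <- v
        }
      }
    }
  }
  all_codes <- unlist(nc, use.names = FALSE)
  all_nodes <- rep(nodes, lengths(nc))
  code_node <- new.env(parent = emptyenv(), size = length(all_codes))
  for (i in seq_along(all_codes)) code_node[[all_codes[i]]] <- all_nodes[i]
  structure(list(nc = nc, all_codes = all_codes, all_nodes = all_nodes,
                 code_node = code_node, nodes = nodes),
            class = "nodecodes_labeling")
}

#' @export
print.nodecodes_labeling <- function(x, ...) {
  cat("<nodecodes_labeling> ", length(x$nodes), " nodes, ",
      length(x$all_codes), " codes (max per node ",
      if (length(x$nc)) max(lengths(x$nc)) else 0L, ")\n", sep = "")
  invisible(x)
}

.check_labeled <- function(lab, node) {
  if (!(node %in% lab$nodes)) {
    stop("lookup error: node '", node, "' is not labeled", call. = FALSE)
  }
}

#' Test strict descendant relation via code prefixes
#'
#' `v` is a strict descendant of `u` iff some code of `u` is a proper
#' component-wise prefix of some code of `v`; a node is never its own
#' descendant.
#'
#' @param lab a `nodecodes_labeling`.
#' @param u,v node ids.
#' @return logical scalar.
#' @export
is_descendant <- function(lab, u, v) {
  stopifnot(inherits(lab, "nodecodes_labeling"))
  .check_labeled(lab, u); .check_labeled(lab, v)
  if (identical(u, v)) return(FALSE)
  cu <- lab$nc[[u]]; cv <- lab$nc[[v]]
  for (x in cu) {
    if (any(startsWith(cv, paste0(x, ".")))) return(TRUE)
  }
  FALSE
}

#' Descendant query by code-prefix scan
#'
#' Returns all strict descendants of `t` by scanning the flattened code
#' table for codes extending a code of `t`; no adjacency traversal is
#' performed.  The number of prefix comparisons made is attached as
#' attribute `"scanned"` and the number of adjacency-list traversals (always
#' 0) as attribute `"traversed"`.
#'
#' @param lab a `nodecodes_labeling`.
#' @param t node id.
#' @return sorted character vector of descendant node ids.
#' @export
descendants_labeled <- function(lab, t) {
  stopifnot(inherits(lab, "nodecodes_labeling"))
  .check_labeled(lab, t)
  hits <- logical(length(lab$all_codes))
  scanned <- 0L
  for (x in lab$nc[[t]]) {
    hits <- hits | startsWith(lab$all_codes, paste0(x, "."))
    scanned <- scanned + length(lab$all_codes)
  }
  out <- sort(unique(lab$all_nodes[hits]))
  out <- setdiff(out, t)
  structure(out, scanned = scanned, traversed = 0L)
}

#' Ancestor query by code-prefix enumeration
#'
#' Every proper component-wise prefix of a code of `t` is the code of
#' exactly one ancestor, so ancestors are read off the code -> node map with
#' no traversal.
#'
#' @inheritParams descendants_labeled
#' @return sorted character vector of strict ancestor node ids.
#' @export
ancestors_labeled <- function(lab, t) {
  stopifnot(inherits(lab, "nodecodes_labeling"))
  .check_labeled(lab, t)
  anc <- character()
  for (x in lab$nc[[t]]) {
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    if (length(parts) <= 1L) next
    for (k in seq_len(length(parts) - 1L)) {
      code <- paste(parts[seq_len(k)], collapse = ".")
      nd <- lab$code_node[[code]]
      if (!is.null(nd)) anc <- c(anc, nd)
    }
  }
  sort(setdiff(unique(anc), t))
}

#' Descendant query by iterative traversal (baseline)
#'
#' Standard reachability over the children adjacency lists, excluding `t`
#' itself.  The number of nodes visited (popped from the frontier,
#' including `t`) is attached as attribute `"visited"` — the work measure
#' for scaling comparisons with the labeled method.
#'
#' @param dag an [sb_dag()].
#' @param t node id.
#' @return sorted character vector of descendant node ids.
#' @export
descendants_iterative <- function(dag, t) {
  stopifnot(inherits(dag, "sb_dag"))
  if (!(t %in% dag$nodes)) {
    stop("lookup error: node '", t, "' not in DAG", call. = FALSE)
  }
  seen <- new.env(parent = emptyenv())
  queue <- t
  visited <- 0L
  out <- character()
  while (length(queue)) {
    u <- queue[[length(queue)]]; queue <- queue[-length(queue)]
    visited <- visited + 1L
    for (v in dag$children[[u]]) {
      if (is.null(seen[[v]])) {
        seen[[v]] <- TRUE
        out <- c(out, v)
        queue <- c(queue, v)
      }
    }
  }
  structure(sort(setdiff(out, t)), visited = visited)
}

#' Ancestor query by iterative traversal (baseline)
#' @inheritParams descendants_iterative
#' @return sorted character vector of strict ancestor node ids.
#' @export
ancestors_iterative <- function(dag, t) {
  stopifnot(inherits(dag, "sb_dag"))
  if (!(t %in% dag$nodes)) {
    stop("lookup error: node '", t, "' not in DAG", call. = FALSE)
  }
  parents <- split(dag$edges$parent, dag$edges$child)
  seen <- new.env(parent = emptyenv())
  queue <- t
  out <- character()
  while (length(queue)) {
    u <- queue[[length(queue)]]; queue <- queue[-length(queue)]
    for (v in parents[[u]]) {
      if (is.null(seen[[v]])) {
        seen[[v]] <- TRUE
        out <- c(out, v)
        queue <- c(queue, v)
      }
    }
  }
  sort(setdiff(out, t))
}

#' Selectivity of a descendant query
#'
#' The proportion of (real) DAG nodes returned by the descendant query for
#' `t`; the virtual source is excluded from numerator and denominator.
#'
#' @param dag an [sb_dag()].
#' @param t node id.
#' @return fraction in `[0, 1]`.
#' @export
selectivity <- function(dag, t) {
  stopifnot(inherits(dag, "sb_dag"))
  if (!length(dag$nodes)) {
    stop("undefined value: selectivity of an empty DAG", call. = FALSE)
  }
  length(descendants_iterative(dag, t)) / length(dag$nodes)
}

#' Compare labeled and iterative descendant queries
#'
#' For each term, asserts that both methods return identical result sets,
#' then reports per-method mean wall time and the mean work counters (codes
#' scanned for the labeled method, nodes visited for the iterative one,
#' adjacency traversals for both).
#'
#' @param dag an [sb_dag()].
#' @param terms node ids to query.
#' @param reps repetitions per term for timing (0 gives an empty table).
#' @param lab optional precomputed labeling (built from `dag` otherwise).
#' @return data frame with columns `method`, `mean_time`, `mean_result_size`,
#'   `mean_visited`, `mean_scanned`, `mean_traversed`.
#' @export
run_query_benchmark <- function(dag, terms, reps = 1L, lab = NULL) {
  stopifnot(inherits(dag, "sb_dag"))
  out_cols <- data.frame(method = character(), mean_time = numeric(),
                         mean_result_size = numeric(),
                         mean_visited = numeric(), mean_scanned = numeric(),
                         mean_traversed = numeric(), stringsAsFactors = FALSE)
  if (reps <= 0L || !length(terms)) return(out_cols)
  if (is.null(lab)) lab <- assign_nodecodes(dag)
  sizes <- numeric(length(terms))
  visited <- numeric(length(terms))
  scanned <- numeric(length(terms))
  for (i in seq_along(terms)) {
    a <- descendants_labeled(lab, terms[[i]])
    b <- descendants_iterative(dag, terms[[i]])
    if (!identical(as.character(a), as.character(b))) {
      stop("result mismatch between labeled and iterative methods at term '",
           terms[[i]], "'", call. = FALSE)
    }
    sizes[i] <- length(a)
    visited[i] <- attr(b, "visited")
    scanned[i] <- attr(a, "scanned")
  }
  t_lab <- system.time(for (r in seq_len(reps)) for (t in terms)
    descendants_labeled(lab, t))[["elapsed"]]
  t_itr <- system.time(for (r in seq_len(reps)) for (t in terms)
    descendants_iterative(dag, t))[["elapsed"]]
  nq <- reps * length(terms)
  rbind(out_cols, data.frame(
    method = c("NodeCodes", "Iterative"),
    mean_time = c(t_lab, t_itr) / nq,
    mean_result_size = rep(mean(sizes), 2),
    mean_visited = c(NA_real_, mean(visited)),
    mean_scanned = c(mean(scanned), NA_real_),
    mean_traversed = c(0, mean(visited)),
    stringsAsFactors = FALSE))
}

#' Export a labeling as a two-column TSV (node, code)
#'
#' The persisted form of the precomputed-NodeCodes table.
#'
#' @param lab a `nodecodes_labeling`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_labeling_tsv <- function(lab, path) {
  stopifnot(inherits(lab, "nodecodes_labeling"))
  utils::write.table(
    data.frame(node = lab$all_nodes, code = lab$all_codes,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
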