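#' Build a molecular graph from an edge list
#'
#' A molecular graph is a simple undirected graph whose vertices are heavy
#' atoms and whose edges are bonds. The graph must be simple (no self-loops,
#' no duplicate edges) and every vertex must have degree at least one; both
#' conditions are enforced here. Vertex labels are opaque strings.
#'
#' @param edges two-column character matrix or data frame; each row is one
#'   undirected edge given by its endpoint labels.
#' @return an [igraph::igraph] undirected graph.
#' @examples
#' g <- molecular_graph(cbind(c("1", "2"), c("2", "3")))
#' igraph::vcount(g)
#' @export
molecular_graph <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L || nrow(edges) < 1L)
    stop("need at least one edge given as a two-column endpoint matrix")
  mode(edges) <- "character"
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop: an atom cannot bond to itself")
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(key))
    stop("duplicate edge: ", key[duplicated(key)][1L])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!igraph::is_connected(g))
    message("molecular graph is disconnected; indices are additive over components")
  g
}

#' Read a molecular graph from edge-list text
#'
#' One edge per line, two whitespace-separated vertex labels. Blank lines and
#' lines starting with `#` are skipped. Self-loops and duplicate edges are
#' errors.
#'
#' @param x path to an edge-list file, or a character vector of lines.
#' @return an undirected [igraph::igraph] graph.
#' @examples
#' read_edge_list(c("1 2", "2 3"))
#' @export
read_edge_list <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else as.character(x)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 1L) stop("edge list contains no edges")
  toks <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(toks) != 2L))
    stop("each edge line must contain exactly two labels")
  molecular_graph(do.call(rbind, toks))
}

#' Build a hydrogen-suppressed molecular graph from a SMILES string
#'
#' One vertex per heavy atom and one edge per bond regardless of bond order;
#' aromatic bonds count once. Hydrogens are never vertices, matching the
#' convention under which degree-based indices are defined for drug
#' molecules. Parsing is delegated to ChemmineR/ChemmineOB.
#'
#' @param smiles a single SMILES string.
#' @return an undirected [igraph::igraph] graph with vertices named by atom
#'   symbol and position (e.g. `"C_1"`).
#' @examples
#' \donttest{
#' g <- graph_from_smiles("CCO")  # ethanol heavy-atom skeleton: path on 3
#' }
#' @export
graph_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("graph_from_smiles() needs the ChemmineR package")
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("unparsable SMILES: ", smiles)
  )
  mol <- sdf[[1L]]
  atoms <- rownames(ChemmineR::atomblock(mol))
  heavy <- atoms[!grepl("^H_", atoms)]
  if (length(heavy) < 2L)
    stop("molecule has fewer than 2 heavy atoms")
  bonds <- ChemmineR::bondblock(mol)
  from <- atoms[bonds[, 1L]]
  to <- atoms[bonds[, 2L]]
  keep <- from %in% heavy & to %in% heavy
  edges <- unique(cbind(pmin(from[keep], to[keep]), pmax(from[keep], to[keep])))
  molecular_graph(edges)
}

#' Degree-based edge partition of a molecular graph
#'
#' Tabulates the edges of `g` by the unordered pair of endpoint degrees
#' `(min(d_u, d_v), max(d_u, d_v))`. The partition is the sufficient
#' statistic for every degree-based topological index: the counts sum to the
#' number of edges and are invariant under vertex relabeling.
#'
#' @param g an undirected [igraph::igraph] graph.
#' @return an object of class `edge_partition`: a data frame with integer
#'   columns `d1 <= d2` and `count`, ordered by `(d1, d2)`.
#' @examples
#' edge_partition(read_edge_list(c("1 2", "2 3")))  # path: {(1,2): 2}
#' @export
edge_partition <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    stop("graph must be simple")
  deg <- igraph::degree(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  a <- pmin(deg[ends[, 1L]], deg[ends[, 2L]])
  b <- pmax(deg[ends[, 1L]], deg[ends[, 2L]])
  tab <- table(a, b)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  out <- data.frame(
    d1 = as.integer(df$a),
    d2 = as.integer(df$b),
    count = as.integer(df$Freq)
  )
  out <- out[order(out$d1, out$d2), ]
  rownames(out) <- NULL
  as_edge_partition(out)
}

#' Coerce to an edge partition
#'
#' Accepts a data frame with columns `d1`, `d2`, `count` (degree pairs are
#' normalized so `d1 <= d2`; repeated pairs are summed) or a named numeric
#' vector with names like `"2-3"`.
#'
#' @param x object to coerce.
#' @return an `edge_partition` data frame.
#' @examples
#' as_edge_partition(c("1-3" = 4, "2-2" = 3, "2-3" = 8, "3-3" = 6))
#' @export
as_edge_partition <- function(x) {
  if (inherits(x, "edge_partition")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    parts <- strsplit(names(x), "-", fixed = TRUE)
    x <- data.frame(
      d1 = as.integer(vapply(parts, `[`, "", 1L)),
      d2 = as.integer(vapply(parts, `[`, "", 2L)),
      count = as.integer(x)
    )
  }
  stopifnot(is.data.frame(x), all(c("d1", "d2", "count") %in% names(x)))
  d1 <- as.integer(pmin(x$d1, x$d2))
  d2 <- as.integer(pmax(x$d1, x$d2))
  count <- as.integer(x$count)
  if (any(is.na(d1)) || any(is.na(d2)) || any(is.na(count)))
    stop("edge partition entries must be integers")
  if (any(d1 < 1L)) stop("degrees must be >= 1")
  if (any(count < 0L)) stop("counts must be non-negative")
  if (length(count) == 0L) {
    out <- data.frame(d1 = integer(), d2 = integer(), count = integer())
    return(structure(out, class = c("edge_partition", "data.frame")))
  }
  agg <- stats::aggregate(count, by = list(d1 = d1, d2 = d2), FUN = sum)
  agg <- agg[agg$x > 0L, ]
  out <- data.frame(d1 = agg$d1, d2 = agg$d2, count = agg$x)
  out <- out[order(out$d1, out$d2), ]
  rownames(out) <- NULL
  structure(out, class = c("edge_partition", "data.frame"))
}

#' @export
print.edge_partition <- function(x, ...) {
  cat("Edge partition:", sum(x$count), "edges\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Number of edges represented by an edge partition
#' @param p an `edge_partition`.
#' @return integer edge count.
#' @export
n_edges <- function(p) {
  p <- as_edge_partition(p)
  sum(p$count)
}
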