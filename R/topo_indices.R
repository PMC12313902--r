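# Registry of degree-based topological indices. Each entry maps an index
# name to its per-edge term f(d_u, d_v); an index value is the sum of
# count * f(d1, d2) over the entries of an edge partition. New degree-based
# indices can be added with register_topo_index() without touching callers.
.index_registry <- new.env(parent = emptyenv())

.register_builtin_indices <- function() {
  terms <- list(
    # first and second Zagreb
    M1 = function(du, dv) du + dv,
    M2 = function(du, dv) du * dv,
    # harmonic
    H = function(du, dv) 2 / (du + dv),
    # forgotten
    F = function(du, dv) du^2 + dv^2,
    # the SS descriptor: per-edge sqrt(du*dv/(du+dv)). The source tables
    # label this "Symmetric Division Degree", but the formula tabulated and
    # used in every worked computation is the one implemented here, which
    # differs from the conventional SDD = (du^2+dv^2)/(du*dv). We follow
    # the tabulated arithmetic.
    SS = function(du, dv) sqrt(du * dv / (du + dv)),
    # atom-bond connectivity; the (1,1) edge term is exactly 0
    ABC = function(du, dv) sqrt((du + dv - 2) / (du * dv)),
    # Randic
    RI = function(du, dv) sqrt(1 / (du * dv)),
    # sum-connectivity
    SC = function(du, dv) sqrt(1 / (du + dv)),
    # geometric-arithmetic
    GA = function(du, dv) 2 * sqrt(du * dv) / (du + dv),
    # hyper-Zagreb; satisfies HZ = F + 2*M2 identically
    HZ = function(du, dv) (du + dv)^2
  )
  for (nm in names(terms)) assign(nm, terms[[nm]], envir = .index_registry)
}

#' Names of the registered degree-based topological indices
#'
#' @return character vector of index identifiers, the ten built-in indices
#'   first (in the conventional order `M1, M2, H, F, SS, ABC, RI, SC, GA,
#'   HZ`) followed by any user-registered ones.
#' @export
index_names <- function() {
  builtin <- c("M1", "M2", "H", "F", "SS", "ABC", "RI", "SC", "GA", "HZ")
  extra <- setdiff(ls(.index_registry), builtin)
  c(builtin, sort(extra))
}

#' Register a new degree-based topological index
#'
#' @param name index identifier.
#' @param term function of two vertex degrees `(du, dv)` returning the
#'   per-edge contribution.
#' @return `name`, invisibly.
#' @export
register_topo_index <- function(name, term) {
  stopifnot(is.character(name), length(name) == 1L, is.function(term))
  assign(name, term, envir = .index_registry)
  invisible(name)
}

#' Evaluate one topological index from an edge partition
#'
#' Computes the sum over partition entries of `count * term(d1, d2)` for
#' the named index. An empty partition gives 0 for every index.
#'
#' @param p an `edge_partition` (or anything [as_edge_partition()] accepts).
#' @param name one of [index_names()].
#' @return a single numeric value.
#' @examples
#' p <- as_edge_partition(c("1-3" = 4, "2-2" = 3, "2-3" = 8, "3-3" = 6))
#' topo_index(p, "M1")   # 104
#' topo_index(p, "ABC")  # 15.0442 (4 d.p.)
#' @export
topo_index <- function(p, name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!exists(name, envir = .index_registry, inherits = FALSE))
    stop("unknown index name: ", name)
  p <- as_edge_partition(p)
  if (nrow(p) == 0L) return(0)
  term <- get(name, envir = .index_registry)
  sum(p$count * term(p$d1, p$d2))
}

#' Evaluate all registered topological indices from an edge partition
#'
#' @param p an `edge_partition` (or anything [as_edge_partition()] accepts).
#' @return named numeric vector over [index_names()]; all values are
#'   non-negative and satisfy the identity `HZ = F + 2*M2` exactly.
#' @examples
#' topo_indices(as_edge_partition(c("2-2" = 6)))  # 6-cycle
#' @export
topo_indices <- function(p) {
  p <- as_edge_partition(p)
  vapply(index_names(), function(nm) topo_index(p, nm), numeric(1))
}

#' Descriptor matrix for a list of molecular graphs
#'
#' Convenience wrapper: computes the edge partition and all indices for each
#' graph.
#'
#' @param graphs list of undirected [igraph::igraph] graphs.
#' @return numeric matrix, one row per graph, one column per index.
#' @export
descriptor_matrix <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1L)
  t(vapply(graphs, function(g) topo_indices(edge_partition(g)),
           numeric(length(index_names()))))
}
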