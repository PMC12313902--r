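# Synthetic study generator: chemical-like connected graphs with bounded
# degree and property values produced as a known polynomial of one
# descriptor plus Gaussian noise, so every pipeline stage can be tested
# against ground truth.

#' Random connected molecular-like graph with bounded degree
#'
#' Builds a uniform-attachment random spanning tree (each new vertex joins
#' a uniformly chosen existing vertex that still has spare valence), then
#' adds each remaining compatible vertex pair as an extra edge with
#' probability `extra_edge_prob`. Connectivity is guaranteed by
#' construction and no degree ever exceeds `max_degree`; the cap of 4
#' mirrors organic heavy-atom valence.
#'
#' @param n_vertices number of atoms, at least 2.
#' @param max_degree maximum vertex degree, between 2 and 4.
#' @param extra_edge_prob probability of adding each admissible non-tree
#'   edge (0 gives a tree).
#' @param seed optional integer seed; the same seed reproduces the same
#'   edge set.
#' @return an undirected [igraph::igraph] graph with vertices `v1..vn`.
#' @export
random_molecular_graph <- function(n_vertices, max_degree = 4L,
                                   extra_edge_prob = 0.15, seed = NULL) {
  stopifnot(n_vertices >= 2L, max_degree >= 2L, max_degree <= 4L,
            extra_edge_prob >= 0, extra_edge_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_vertices)
  deg <- integer(n)
  edges <- matrix(0L, 0L, 2L)
  # spanning tree: a tree on k vertices with cap >= 2 always has a vertex
  # with spare valence (sum of degrees 2(k-1) < 2k <= cap*k)
  for (v in 2:n) {
    open <- which(deg[seq_len(v - 1L)] < max_degree)
    u <- if (length(open) == 1L) open else sample(open, 1L)
    edges <- rbind(edges, c(u, v))
    deg[u] <- deg[u] + 1L
    deg[v] <- deg[v] + 1L
  }
  if (extra_edge_prob > 0 && n > 2L) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    in_tree <- paste(edges[, 1L], edges[, 2L]) # tree rows already have u < v
    pairs <- pairs[!paste(pairs[, 1L], pairs[, 2L]) %in% in_tree, , drop = FALSE]
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    add <- stats::runif(nrow(pairs)) < extra_edge_prob
    for (k in seq_len(nrow(pairs))) {
      if (!add[k]) next
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (deg[i] < max_degree && deg[j] < max_degree) {
        edges <- rbind(edges, c(i, j))
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
  }
  molecular_graph(cbind(paste0("v", edges[, 1L]), paste0("v", edges[, 2L])))
}

#' Simulate property values from a polynomial of a descriptor
#'
#' `y_j = beta0 + beta1 x_j + beta2 x_j^2 + beta3 x_j^3 + e_j` with
#' `e_j ~ N(0, sigma^2)`. With `sigma = 0` the values are the exact
#' polynomial.
#'
#' @param descriptor_values numeric vector of descriptor values.
#' @param beta coefficient vector of length up to 4 (`beta0` first;
#'   shorter vectors are zero-padded).
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed optional integer seed for the noise draws.
#' @return numeric vector of simulated property values.
#' @export
simulate_property <- function(descriptor_values, beta, sigma = 0, seed = NULL) {
  stopifnot(is.numeric(descriptor_values), is.numeric(beta),
            length(beta) >= 1L, length(beta) <= 4L, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  beta <- c(beta, rep(0, 4L - length(beta)))
  x <- descriptor_values
  y <- beta[1L] + beta[2L] * x + beta[3L] * x^2 + beta[4L] * x^3
  if (sigma > 0) y <- y + stats::rnorm(length(x), 0, sigma)
  y
}

#' Generate a full synthetic study
#'
#' End-to-end: random bounded-degree graphs, their edge partitions and
#' descriptor matrix, and a property simulated as a polynomial of one
#' chosen descriptor plus Gaussian noise. The master seed determines the
#' whole study; descriptor matrices that are numerically rank-deficient
#' are re-drawn (with a message) so downstream fits are well posed.
#'
#' @param m_molecules number of molecules.
#' @param n_vertices_range integer range the per-molecule atom counts are
#'   drawn from.
#' @param max_degree,extra_edge_prob passed to [random_molecular_graph()].
#' @param driver_index descriptor driving the response (default `"M1"`).
#' @param beta true polynomial coefficients (`beta0` first, up to 4).
#' @param sigma Gaussian noise standard deviation.
#' @param seed master seed; regenerating with the same seed reproduces the
#'   identical study.
#' @return object of class `synthetic_study`: list with `molecules`,
#'   `descriptors` (`m x 10` matrix), `properties`, `true_coefficients`,
#'   `noise_sd`, `driver_index`, `seed`.
#' @export
make_dataset <- function(m_molecules, n_vertices_range = c(10L, 30L),
                         max_degree = 4L, extra_edge_prob = 0.15,
                         driver_index = "M1", beta = c(5, 2), sigma = 1,
                         seed = 1L) {
  stopifnot(m_molecules >= 1L, length(n_vertices_range) == 2L,
            n_vertices_range[1L] >= 2L,
            n_vertices_range[2L] >= n_vertices_range[1L],
            driver_index %in% index_names())
  for (attempt in 1:20) {
    set.seed(seed + (attempt - 1L) * 1000003L)
    sizes <- sample(n_vertices_range[1L]:n_vertices_range[2L],
                    m_molecules, replace = TRUE)
    molecules <- lapply(sizes, function(n)
      random_molecular_graph(n, max_degree, extra_edge_prob))
    descriptors <- descriptor_matrix(molecules)
    # The descriptor matrix carries the exact linear dependence
    # HZ = F + 2*M2, so its maximal achievable column rank is ncol - 1;
    # require that maximum (plus enough distinct values per column for
    # cubic fits) and re-draw the rare degenerate sample.
    distinct_ok <- all(apply(descriptors, 2L, function(v) length(unique(v))) >= 4L)
    rank_ok <- TRUE
    if (m_molecules >= ncol(descriptors) - 1L) {
      sv <- svd(scale(descriptors), nu = 0, nv = 0)$d
      rank_ok <- sum(sv > max(sv) * 1e-10) >= ncol(descriptors) - 1L
    }
    if (!(distinct_ok && rank_ok) && m_molecules >= 5L) {
      message("degenerate descriptor draw; re-drawing")
      next
    }
    break
  }
  properties <- simulate_property(descriptors[, driver_index], beta, sigma)
  structure(list(molecules = molecules, descriptors = descriptors,
                 properties = properties,
                 true_coefficients = c(beta, rep(0, 4L - length(beta))),
                 noise_sd = sigma, driver_index = driver_index,
                 seed = as.integer(seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(x$molecules), "molecules; response =",
      "polynomial of", x$driver_index, "with sigma =", x$noise_sd,
      "(seed", paste0(x$seed, ")\n"))
  invisible(x)
}
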