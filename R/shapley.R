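# Exact Shapley-value attribution of model predictions to features, by
# full enumeration of the 2^d feature coalitions. The value function of a
# coalition S is the model prediction on the explained sample with the
# features outside S replaced by the background per-feature mean (a
# deterministic mean-imputation approximation of interventional
# attribution). With d = 10 descriptors the enumeration costs 1024
# evaluations per sample, done in one batched model call.

.coalition_masks <- function(d) {
  # 2^d x d logical matrix; row r encodes the binary expansion of r-1 with
  # feature j as bit j-1, so S and S + {j} differ by a row offset of 2^(j-1)
  as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
}

#' Exact Shapley attribution for one sample
#'
#' Computes, for every feature `i`, the Shapley value
#' `phi_i = sum over S not containing i of |S|! (d-|S|-1)! / d! *
#' (v(S + i) - v(S))` with value function `v(S)` equal to the model
#' prediction on `x` with features outside `S` replaced by the background
#' mean. Satisfies local accuracy: `base_value + sum(phi)` equals the model
#' prediction at `x`.
#'
#' @param predict_fn function taking a numeric matrix (rows are samples)
#'   and returning a numeric vector of predictions.
#' @param background numeric matrix of background samples (its column means
#'   define the imputation values).
#' @param x numeric vector, the sample to explain.
#' @return list with `phi` (named by the columns of `background` when
#'   available) and `base_value` (`v` of the empty coalition).
#' @export
exact_shapley <- function(predict_fn, background, x) {
  background <- as.matrix(background)
  d <- length(x)
  stopifnot(ncol(background) == d, nrow(background) >= 1L)
  if (d > 20L) stop("too many features for exact enumeration (d > 20)")
  masks <- .coalition_masks(d)
  bg <- colMeans(background)
  Xc <- matrix(bg, nrow(masks), d, byrow = TRUE)
  Xc[masks] <- matrix(x, nrow(masks), d, byrow = TRUE)[masks]
  v <- predict_fn(Xc)
  if (length(v) != nrow(masks) || anyNA(v) || any(!is.finite(v)))
    stop("predict_fn must return one finite value per row")
  sizes <- rowSums(masks)
  # weight by coalition size s: s! (d-s-1)! / d!
  wt <- exp(lfactorial(0:(d - 1L)) + lfactorial(d - 1L - 0:(d - 1L)) - lfactorial(d))
  phi <- numeric(d)
  for (i in seq_len(d)) {
    without <- which(!masks[, i])
    with_i <- without + 2L^(i - 1L)
    phi[i] <- sum(wt[sizes[without] + 1L] * (v[with_i] - v[without]))
  }
  names(phi) <- colnames(background)
  list(phi = phi, base_value = v[1L])
}

#' Exact Shapley attributions for a set of samples
#'
#' @param predict_fn as in [exact_shapley()].
#' @param background numeric matrix defining the mean-imputation background.
#' @param X numeric matrix of samples to explain (defaults to the
#'   background itself, the usual choice when explaining the training set).
#' @return object of class `shapley_attribution`: list with `phi`
#'   (`nrow(X) x d` matrix), `base_value` and `importance` (mean absolute
#'   `phi` per feature).
#' @export
shapley_attributions <- function(predict_fn, background, X = background) {
  X <- as.matrix(X)
  per_sample <- apply(X, 1L, function(x) exact_shapley(predict_fn, background, x),
                      simplify = FALSE)
  phi <- do.call(rbind, lapply(per_sample, `[[`, "phi"))
  rownames(phi) <- rownames(X)
  structure(list(phi = phi,
                 base_value = per_sample[[1L]]$base_value,
                 importance = colMeans(abs(phi))),
            class = "shapley_attribution")
}

#' Global feature importance from Shapley attributions
#'
#' Features ranked by mean absolute attribution, descending; ties broken by
#' original feature order.
#'
#' @param attributions a `shapley_attribution` (or a bare `phi` matrix).
#' @return data frame with `feature`, `mean_abs_phi`, `rank`.
#' @export
global_importance <- function(attributions) {
  imp <- if (inherits(attributions, "shapley_attribution"))
    attributions$importance else colMeans(abs(as.matrix(attributions)))
  if (is.null(names(imp))) names(imp) <- paste0("x", seq_along(imp))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = names(imp)[ord],
             mean_abs_phi = unname(imp[ord]),
             rank = seq_along(imp),
             stringsAsFactors = FALSE)
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat("Shapley attributions for", nrow(x$phi), "samples,",
      ncol(x$phi), "features; base value", format(x$base_value, digits = 6), "\n")
  print(utils::head(global_importance(x), 5L))
  invisible(x)
}
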