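#' STAPLE fusion of multi-rater segmentations
#'
#' Simultaneous Truth and Performance Level Estimation: an EM algorithm that
#' fuses binary segmentations from several raters into a posterior
#' probability map of the true segmentation while estimating every rater's
#' sensitivity `p_j` and specificity `q_j`.
#'
#' With rater decisions `D_ij` (1 = rater j marked pixel i foreground) and
#' foreground prior `pi_i`, the E-step computes
#' `W_i = a_i / (a_i + b_i)` with
#' `a_i = pi_i prod_j p_j^D_ij (1 - p_j)^(1 - D_ij)` and
#' `b_i = (1 - pi_i) prod_j (1 - q_j)^D_ij q_j^(1 - D_ij)`;
#' the M-step re-estimates
#' `p_j = sum_i W_i D_ij / sum_i W_i` and
#' `q_j = sum_i (1 - W_i)(1 - D_ij) / sum_i (1 - W_i)`.
#' Products are accumulated in log space; the observed-data log-likelihood
#' `sum_i log(a_i + b_i)` is tracked and is non-decreasing over iterations.
#'
#' @param stack a `rater_stack` (see [make_rater_stack()]) or plain list of
#'   identically shaped binary masks from at least two raters.
#' @param prior scalar foreground prior in (0, 1), or `NULL` to use the mean
#'   foreground fraction across raters (the default, common practice).
#' @param max_iters EM iteration cap.
#' @param tol convergence tolerance on the largest change in any `p_j`, `q_j`.
#' @return an object of class `staple_fit`: posterior map `W`, per-rater
#'   `p` and `q`, `n_em_iters`, `converged`, `log_lik` trace and the prior.
#' @export
run_staple <- function(stack, prior = NULL, max_iters = 100, tol = 1e-6) {
  masks <- if (inherits(stack, "rater_stack")) stack$masks else stack
  J <- length(masks)
  if (J < 2) stop("STAPLE needs at least two raters")
  dims <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), dims), logical(1))))
    stop("all rater masks must share the same shape")
  D <- vapply(masks, as.numeric, numeric(prod(dims)))   # pixels x raters
  if (is.null(prior)) prior <- mean(D)
  if (prior <= 0 || prior >= 1)
    stop("foreground prior must lie strictly inside (0, 1)")
  eps <- 1e-6
  degenerate <- colMeans(D) %in% c(0, 1)
  if (any(degenerate))
    warning("rater(s) ", paste(which(degenerate), collapse = ", "),
            " are all-background or all-foreground; clamping their parameters")
  p <- rep(1 - 1e-4, J)
  q <- rep(1 - 1e-4, J)
  log_lik <- numeric(0)
  converged <- FALSE
  n_it <- 0L
  W <- NULL
  for (it in seq_len(max_iters)) {
    n_it <- it
    lp <- log(pmin(pmax(p, eps), 1 - eps)); l1p <- log(pmin(pmax(1 - p, eps), 1 - eps))
    lq <- log(pmin(pmax(q, eps), 1 - eps)); l1q <- log(pmin(pmax(1 - q, eps), 1 - eps))
    la <- log(prior) + D %*% lp + (1 - D) %*% l1p
    lb <- log1p(-prior) + D %*% l1q + (1 - D) %*% lq
    m <- pmax(la, lb)
    log_lik <- c(log_lik, sum(m + log(exp(la - m) + exp(lb - m))))
    W <- 1 / (1 + exp(lb - la))
    sw <- sum(W); swc <- sum(1 - W)
    p_new <- as.numeric(crossprod(D, W)) / sw
    q_new <- as.numeric(crossprod(1 - D, 1 - W)) / swc
    p_new <- pmin(pmax(p_new, eps), 1 - eps)
    q_new <- pmin(pmax(q_new, eps), 1 - eps)
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new; q <- q_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(W = matrix(W, dims[1], dims[2]), p = p, q = q,
                 n_em_iters = n_it, converged = converged,
                 log_lik = log_lik, prior = prior,
                 rater_ids = if (inherits(stack, "rater_stack")) stack$rater_ids
                 else paste0("rater", seq_len(J))),
            class = "staple_fit")
}

#' @export
print.staple_fit <- function(x, ...) {
  cat(sprintf("<staple_fit> %d raters, %d EM iterations (%s)\n",
              length(x$p), x$n_em_iters,
              if (x$converged) "converged" else "not converged"))
  cat("sensitivity p:", paste(sprintf("%.4f", x$p), collapse = " "), "\n")
  cat("specificity q:", paste(sprintf("%.4f", x$q), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.staple_fit <- function(object, ...) {
  out <- data.frame(rater = object$rater_ids,
                    sensitivity = object$p, specificity = object$q)
  attr(out, "n_em_iters") <- object$n_em_iters
  attr(out, "converged") <- object$converged
  out
}

#' @export
coef.staple_fit <- function(object, ...) {
  stats::setNames(c(object$p, object$q),
                  c(paste0("p_", seq_along(object$p)), paste0("q_", seq_along(object$q))))
}

#' Morphological cleanup of a binary segmentation
#'
#' One-pixel opening (removes isolated foreground specks) followed by a
#' one-pixel closing (fills pinholes). Human segmentations are spatially
#' coherent; emulated per-pixel raters introduce isolated errors that this
#' standard cleanup removes before a fused mask is used as a registration
#' reference.
#'
#' @param mask binary mask matrix.
#' @param radius structuring-element half-size in pixels (brush is
#'   `2 * radius + 1` wide).
#' @return a cleaned binary mask.
#' @export
clean_binary_mask <- function(mask, radius = 1) {
  brush <- EBImage::makeBrush(2 * radius + 1, "box")
  m <- EBImage::closing(EBImage::opening(mask, brush), brush)
  (m > 0.5) * 1
}

#' Binarize a STAPLE posterior map
#'
#' @param fit a `staple_fit`.
#' @param level probability threshold in (0, 1); pixels with `W >= level`
#'   become foreground (ties included).
#' @return a binary mask matrix.
#' @export
threshold_consensus <- function(fit, level = 0.5) {
  stopifnot(inherits(fit, "staple_fit"), level > 0, level < 1)
  (fit$W >= level) * 1
}
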