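#' Construct and validate a cell-type reference matrix
#'
#' A markers-by-cell-types matrix of expected methylation-like signal in
#' [0, 1], with at least as many markers as cell types and full column
#' rank, as used for reference-based deconvolution of leukocyte
#' composition.
#'
#' @param m numeric matrix (markers in rows, cell types in columns);
#'   `colnames` are the cell-type names, `rownames` the marker ids.
#' @return the validated matrix with class `reference_matrix`.
#' @export
reference_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop("reference matrix entries must lie in [0, 1]")
  }
  if (nrow(m) < ncol(m)) stop("need at least as many markers as cell types")
  if (qr(m)$rank < ncol(m)) stop("reference matrix is rank deficient")
  if (is.null(colnames(m))) colnames(m) <- paste0("type", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("marker", seq_len(nrow(m)))
  class(m) <- c("reference_matrix", class(m))
  m
}

# Active-set solver for min ||p - R w||^2  s.t.  w >= 0, sum(w) = 1.
# Solves the equality-constrained KKT system on the free set, walks back
# along the feasible segment when a free weight would go negative
# (Lawson-Hanson style), and frees the active weight with the most
# negative Lagrange multiplier until all multipliers are nonnegative.
simplex_ls <- function(R, p, tol = 1e-10, max_iter = 1e4) {
  m <- ncol(R)
  Q <- crossprod(R)
  cvec <- drop(crossprod(R, p))
  w <- rep(1 / m, m)
  free <- rep(TRUE, m)
  solve_free <- function(free) {
    nf <- sum(free)
    K <- rbind(cbind(Q[free, free, drop = FALSE], 1),
               c(rep(1, nf), 0))
    sol <- solve(K, c(cvec[free], 1))
    list(w = sol[seq_len(nf)], mu = sol[nf + 1L])
  }
  for (it in seq_len(max_iter)) {
    sol <- solve_free(free)
    w_new <- numeric(m)
    w_new[free] <- sol$w
    if (all(w_new[free] >= -tol)) {
      w <- pmax(w_new, 0)
      # KKT multipliers of the active bounds; the system solves
      # Q w + mu = c, so the bound multiplier is (Qw - c)_i + mu
      lambda <- (Q %*% w - cvec) + sol$mu
      active <- !free
      if (!any(active) || all(lambda[active] >= -tol)) {
        return(w / sum(w))
      }
      idx <- which(active)[which.min(lambda[active])]
      free[idx] <- TRUE
    } else {
      # step from w toward w_new, stopping at the first zero crossing
      d <- w_new - w
      blocking <- free & d < 0
      alpha <- min(-w[blocking] / d[blocking])
      w <- w + alpha * d
      hit <- which(free & w <= tol & d < 0)
      w[hit] <- 0
      free[hit] <- FALSE
      if (!any(free)) stop("constrained solver: all weights became active")
    }
  }
  stop("constrained solver failed to converge within ", max_iter, " iterations")
}

#' Estimate cell-type fractions by constrained projection
#'
#' Reference-based deconvolution of a methylation-like marker profile:
#' solves `min || profile - reference %*% w ||^2` subject to `w >= 0` and
#' `sum(w) = 1`, so the solution is a composition on the probability
#' simplex directly usable as regression covariates (with one fraction
#' dropped to avoid collinearity). The solver is an active-set quadratic
#' minimizer converging to the KKT point (tolerance 1e-10, at most 1e4
#' iterations).
#'
#' @param profile numeric marker vector in [0, 1], aligned with the
#'   reference's rows (a named vector is re-ordered by marker id).
#' @param reference a [reference_matrix()].
#' @param sample_id optional id recorded on the result.
#' @return object of class `cell_fractions`: `sample_id`, `fractions`
#'   (named, summing to 1), `residual_norm`.
#' @export
estimate_fractions <- function(profile, reference, sample_id = NA_character_) {
  reference <- reference_matrix(unclass(reference))
  if (!is.null(names(profile))) {
    if (!setequal(names(profile), rownames(reference))) {
      stop("profile markers do not match the reference markers")
    }
    profile <- profile[rownames(reference)]
  } else if (length(profile) != nrow(reference)) {
    stop("profile length ", length(profile), " does not match ",
         nrow(reference), " reference markers")
  }
  if (any(!is.finite(profile)) || any(profile < 0) || any(profile > 1)) {
    stop("profile values must lie in [0, 1]")
  }
  w <- simplex_ls(unclass(reference), as.numeric(profile))
  names(w) <- colnames(reference)
  structure(list(sample_id = sample_id, fractions = w,
                 residual_norm = sqrt(sum((profile - unclass(reference) %*% w)^2))),
            class = "cell_fractions")
}

#' @export
print.cell_fractions <- function(x, ...) {
  cat("Estimated cell fractions",
      if (!is.na(x$sample_id)) paste0("for ", x$sample_id), "\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Estimate fractions for a matrix of profiles
#'
#' @param profiles markers-by-samples matrix (or samples in columns of a
#'   data frame).
#' @param reference a [reference_matrix()].
#' @return data frame: one row per sample, columns `sample_id` plus one
#'   per cell type.
#' @export
estimate_fractions_matrix <- function(profiles, reference) {
  profiles <- as.matrix(profiles)
  ids <- colnames(profiles)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(profiles)))
  rows <- lapply(seq_len(ncol(profiles)), function(j) {
    f <- estimate_fractions(profiles[, j], reference, sample_id = ids[j])
    as.data.frame(c(list(sample_id = ids[j]), as.list(f$fractions)),
                  stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
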