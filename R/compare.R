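#' One-tailed paired t-test
#'
#' Paired t on the differences `x_b - x_a`. `direction = "less"` tests the
#' hypothesis that `x_b` is smaller than `x_a` (the default for comparing
#' vibration-ON variability against OFF); `"greater"` the reverse;
#' `"two.sided"` is available for supplementary mean comparisons. Constant
#' nonzero differences (zero SD) are reported as `t = +/-Inf` with p of 0 or
#' 1 according to the direction.
#'
#' @param x_a,x_b Paired samples (same participants, equal length `>= 3`).
#' @param direction Alternative hypothesis for `x_b` relative to `x_a`.
#' @return Tibble with `t`, `df`, `p`.
#' @export
paired_t_one_tailed <- function(x_a, x_b,
                                direction = c("less", "greater", "two.sided")) {
  direction <- match.arg(direction)
  check_paired(x_a, x_b)
  d <- x_b - x_a
  if (sd(d) == 0) {
    if (all(d == 0)) return(tibble(t = 0, df = length(d) - 1, p = 0.5))
    t_val <- sign(d[1]) * Inf
    p <- switch(direction,
                less = if (d[1] < 0) 0 else 1,
                greater = if (d[1] > 0) 0 else 1,
                two.sided = 0)
    return(tibble(t = t_val, df = length(d) - 1, p = p))
  }
  ht <- t.test(x_b, x_a, paired = TRUE, alternative = direction)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Wilcoxon signed-rank test
#'
#' Signed-rank test on the paired differences `x_b - x_a`, used when the
#' normality or homogeneity-of-variance checks fail. `V` is the sum of the
#' ranks of the positive differences; the p-value is exact for `n <= 25`
#' non-zero differences (no ties) and a Normal approximation with
#' continuity correction otherwise.
#'
#' @inheritParams paired_t_one_tailed
#' @return Tibble with `V`, `p`, `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(x_a, x_b,
                                 direction = c("less", "greater", "two.sided")) {
  direction <- match.arg(direction)
  check_paired(x_a, x_b)
  d <- x_b - x_a
  nz <- sum(d != 0)
  if (nz == 0) {
    abort("All paired differences are zero; the signed-rank test is undefined.",
          class = "gaitvar_degenerate_error")
  }
  ht <- suppressWarnings(
    wilcox.test(x_b, x_a, paired = TRUE, alternative = direction,
                exact = nz <= 25, correct = TRUE)
  )
  tibble(V = unname(ht$statistic), p = ht$p.value, n_nonzero = nz)
}

check_paired <- function(x_a, x_b) {
  if (length(x_a) != length(x_b)) {
    abort("Samples are not paired: unequal lengths.",
          class = "gaitvar_pairing_error")
  }
  if (length(x_a) < 3) {
    abort("Need at least 3 pairs.", class = "gaitvar_insufficient_data_error")
  }
  invisible(TRUE)
}

#' Distributional assumption checks
#'
#' `normality_check()` is the Shapiro-Wilk test; `variance_check()` is
#' Bartlett's test of homogeneity of variance between two groups.
#'
#' @param x Numeric sample (`n >= 3`, not constant).
#' @return `normality_check()`: tibble with `W`, `p`.
#' @export
normality_check <- function(x) {
  if (length(unique(x)) < 2) {
    abort("Constant input; normality test is degenerate.",
          class = "gaitvar_degenerate_error")
  }
  ht <- shapiro.test(x)
  tibble(W = unname(ht$statistic), p = ht$p.value)
}

#' @rdname normality_check
#' @param x_a,x_b The two groups.
#' @return `variance_check()`: tibble with `K2`, `df`, `p`.
#' @export
variance_check <- function(x_a, x_b) {
  if (sd(x_a) == 0 && sd(x_b) == 0) {
    abort("Both groups are constant; variance test is degenerate.",
          class = "gaitvar_degenerate_error")
  }
  ht <- bartlett.test(list(x_a, x_b))
  tibble(K2 = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Two-group MANOVA with Wilks' Lambda
#'
#' One-way two-group multivariate analysis of variance on `p` response
#' variables. Wilks' Lambda is the determinant ratio
#' `det(E) / det(E + H)` of the within-group (`E`) and between-group (`H`)
#' sums-of-squares-and-cross-products matrices. For two groups the exact
#' transform `F = ((1 - Lambda) / Lambda) * ((N - p - 1) / p)` holds with
#' `df = (p, N - p - 1)`. With 10 participants per condition and a 10-point
#' phase grid this gives df (10, 9).
#'
#' A paired one-sample (Hotelling) variant on the differences is available
#' via `mode = "paired"`; note it requires `n >= p + 1` participants and so
#' cannot be applied to 10 participants with a 10-point grid.
#'
#' @param x_a,x_b Numeric matrices, participants x variables (same columns).
#' @param mode `"two_group"` (default) or `"paired"`.
#' @return Tibble with `lambda`, `F`, `df1`, `df2`, `p`.
#' @export
manova_two_group <- function(x_a, x_b, mode = c("two_group", "paired")) {
  mode <- match.arg(mode)
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  if (ncol(x_a) != ncol(x_b)) abort("Groups must have the same variables.")
  p <- ncol(x_a)
  if (mode == "paired") {
    if (nrow(x_a) != nrow(x_b)) {
      abort("Paired mode needs matched rows.", class = "gaitvar_pairing_error")
    }
    d <- x_b - x_a
    n <- nrow(d)
    if (n < p + 1) {
      abort(sprintf("Paired MANOVA needs n >= p + 1 (%d >= %d).", n, p + 1))
    }
    dbar <- colMeans(d)
    S <- stats::cov(d)
    T2 <- tryCatch(n * drop(t(dbar) %*% solve(S, dbar)),
                   error = function(e) abort(
                     "Singular covariance matrix in paired MANOVA.",
                     class = "gaitvar_rank_error"))
    F_val <- (n - p) / (p * (n - 1)) * T2
    lambda <- 1 / (1 + T2 / (n - 1))
    return(tibble(lambda = lambda, F = F_val, df1 = p, df2 = n - p,
                  p = pf(F_val, p, n - p, lower.tail = FALSE)))
  }
  n1 <- nrow(x_a); n2 <- nrow(x_b); N <- n1 + n2
  if (N < p + 2) abort(sprintf("Need N >= p + 2 (%d >= %d).", N, p + 2))
  m1 <- colMeans(x_a); m2 <- colMeans(x_b)
  m <- (n1 * m1 + n2 * m2) / N
  H <- n1 * tcrossprod(m1 - m) + n2 * tcrossprod(m2 - m)
  E <- crossprod(sweep(x_a, 2, m1)) + crossprod(sweep(x_b, 2, m2))
  if (max(abs(H)) <= 1e-12 * max(max(abs(E)), 1)) {
    # no between-group scatter at all: Lambda = det(E)/det(E + 0) = 1,
    # the no-effect limit, regardless of the conditioning of E
    return(tibble(lambda = 1, F = 0, df1 = p, df2 = N - p - 1, p = 1))
  }
  sv <- svd(E, nu = 0, nv = 0)$d
  if (min(sv) < max(sv) * 1e-10 || !all(is.finite(sv))) {
    bad <- which(abs(diag(E)) < max(abs(diag(E))) * 1e-10)
    abort(paste0("Within-group SSCP matrix is rank deficient",
                 if (length(bad) > 0)
                   paste0(" (degenerate column(s) ",
                          paste(bad, collapse = ", "), ")") else "", "."),
          class = "gaitvar_rank_error")
  }
  lambda <- det(E) / det(E + H)
  F_val <- (1 - lambda) / lambda * (N - p - 1) / p
  tibble(lambda = lambda, F = F_val, df1 = p, df2 = N - p - 1,
         p = pf(F_val, p, N - p - 1, lower.tail = FALSE))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise type-I error rate.
#' @param m Number of comparisons.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 10)  # 0.005
bonferroni_threshold <- function(alpha, m) {
  if (m < 1 || alpha <= 0 || alpha >= 1) abort("Need m >= 1 and 0 < alpha < 1.")
  alpha / m
}

#' Compare MAD profiles between two conditions
#'
#' Implements the gated two-condition comparison protocol for a profile
#' quantity on a phase grid: (1) a two-group MANOVA on the grid values gates
#' the family at `alpha`; (2) if the gate passes, each grid point is tested
#' with a one-tailed paired t-test, replaced by the Wilcoxon signed-rank
#' test whenever Shapiro-Wilk normality fails in either condition or
#' Bartlett's homogeneity of variance fails (both at `assumption_alpha`);
#' (3) per-point significance is declared at the Bonferroni threshold
#' `alpha / m`, `m` being the number of grid points. The full decision
#' trace (assumption statistics and test routing) is retained.
#'
#' @param profiles_a,profiles_b Tidy profile tibbles as from [mad_profile()]
#'   (columns `participant`, `phase`, and the value column), one row per
#'   participant per phase, matched participants. Condition A is the
#'   reference (e.g. vibration OFF), B the treatment (ON).
#' @param value Column to compare, `"mad"` (default) or `"mean"`.
#' @param direction Alternative for B relative to A per grid point;
#'   the default `"less"` encodes the hypothesis that variability is
#'   reduced in condition B.
#' @param alpha Gate and family-wise level (default 0.05).
#' @param assumption_alpha Level of the assumption checks (default 0.05).
#' @param mode MANOVA mode, see [manova_two_group()].
#' @return An object of class `gait_comparison`: list with `manova`,
#'   `points` (per-grid-point tibble), `assumptions`, `threshold`, `alpha`,
#'   `m`, `gate_passed`, `value`, `direction`.
#' @export
compare_conditions <- function(profiles_a, profiles_b, value = "mad",
                               direction = c("less", "greater", "two.sided"),
                               alpha = 0.05, assumption_alpha = 0.05,
                               mode = "two_group") {
  direction <- match.arg(direction)
  wa <- profiles_to_matrix(profiles_a, value)
  wb <- profiles_to_matrix(profiles_b, value)
  if (!identical(colnames(wa), colnames(wb))) {
    abort("Conditions use different phase grids.", class = "gaitvar_pairing_error")
  }
  if (!identical(rownames(wa), rownames(wb))) {
    abort("Participant sets differ between conditions.",
          class = "gaitvar_pairing_error")
  }
  grid <- as.integer(colnames(wa))
  m <- length(grid)
  threshold <- bonferroni_threshold(alpha, m)
  man <- manova_two_group(wa, wb, mode = mode)
  gate <- man$p < alpha

  assumptions <- purrr::map_dfr(seq_len(m), function(j) {
    sw_a <- safe_check(normality_check(wa[, j]), c("W", "p"))
    sw_b <- safe_check(normality_check(wb[, j]), c("W", "p"))
    bt <- safe_check(variance_check(wa[, j], wb[, j]), c("K2", "p"))
    tibble(phase = grid[j],
           shapiro_W_a = sw_a[1], shapiro_p_a = sw_a[2],
           shapiro_W_b = sw_b[1], shapiro_p_b = sw_b[2],
           bartlett_K2 = bt[1], bartlett_p = bt[2])
  })

  points <- purrr::map_dfr(seq_len(m), function(j) {
    if (!gate) {
      return(tibble(phase = grid[j], test = NA_character_,
                    statistic = NA_real_, p = NA_real_, significant = FALSE))
    }
    asm <- assumptions[j, ]
    use_wilcoxon <- isTRUE(asm$shapiro_p_a < assumption_alpha) ||
      isTRUE(asm$shapiro_p_b < assumption_alpha) ||
      isTRUE(asm$bartlett_p < assumption_alpha)
    if (use_wilcoxon) {
      res <- wilcoxon_signed_rank(wa[, j], wb[, j], direction)
      tibble(phase = grid[j], test = "wilcoxon",
             statistic = res$V, p = res$p, significant = res$p < threshold)
    } else {
      res <- paired_t_one_tailed(wa[, j], wb[, j], direction)
      tibble(phase = grid[j], test = "t",
             statistic = res$t, p = res$p, significant = res$p < threshold)
    }
  })

  structure(list(manova = man, points = points, assumptions = assumptions,
                 threshold = threshold, alpha = alpha, m = m,
                 gate_passed = gate, value = value, direction = direction),
            class = "gait_comparison")
}

safe_check <- function(expr, names) {
  out <- tryCatch(expr, error = function(e) NULL)
  if (is.null(out)) rep(NA_real_, length(names)) else as.numeric(out[1, names])
}

profiles_to_matrix <- function(profiles, value) {
  need <- c("participant", "phase", value)
  if (!all(need %in% names(profiles))) {
    abort(paste0("Profiles need columns: ", paste(need, collapse = ", ")))
  }
  w <- profiles |>
    dplyr::select(dplyr::all_of(c("participant", "phase", value))) |>
    tidyr::pivot_wider(names_from = "phase", values_from = dplyr::all_of(value)) |>
    dplyr::arrange(.data$participant)
  mat <- as.matrix(w[setdiff(names(w), "participant")])
  rownames(mat) <- as.character(w$participant)
  mat[, order(as.integer(colnames(mat))), drop = FALSE]
}

#' @export
print.gait_comparison <- function(x, ...) {
  man <- x$manova
  cat(sprintf("Two-condition comparison of `%s` (direction: %s)\n",
              x$value, x$direction))
  cat(sprintf("MANOVA gate: F(%d, %d) = %.2f, Wilks' Lambda = %.2f, p = %.3g [%s]\n",
              man$df1, man$df2, man$F, man$lambda, man$p,
              if (x$gate_passed) "passed" else "not passed"))
  cat(sprintf("Per-point threshold (Bonferroni %g/%d): %g\n",
              x$alpha, x$m, x$threshold))
  if (x$gate_passed) {
    print(as.data.frame(x$points), row.names = FALSE)
  } else {
    cat("Per-point tests not run (gate not passed).\n")
  }
  invisible(x)
}

#' Tidy the per-grid-point comparison results
#'
#' @param x A `gait_comparison` object.
#' @param ... Unused.
#' @return `tidy()`: the per-point tibble (`phase`, `test`, `statistic`,
#'   `p`, `significant`); `glance()`: a one-row tibble with the MANOVA gate
#'   and protocol settings.
#' @importFrom generics tidy
#' @method tidy gait_comparison
#' @export
tidy.gait_comparison <- function(x, ...) x$points

#' @rdname tidy.gait_comparison
#' @importFrom generics glance
#' @method glance gait_comparison
#' @export
glance.gait_comparison <- function(x, ...) {
  dplyr::bind_cols(
    x$manova,
    tibble(gate_passed = x$gate_passed, threshold = x$threshold,
           alpha = x$alpha, m = x$m, value = x$value,
           direction = x$direction)
  )
}

#' @export
generics::tidy

#' @export
generics::glance
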