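# Permutational multivariate ANOVA (Euclidean distance, type III SS),
# permutation and Monte Carlo p-values, pairwise comparisons, Welch's t.

# Gower-centred matrix from squared Euclidean distances:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n)
gower_matrix <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  rm_ <- rowMeans(a)
  a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
}

hat_matrix <- function(x) {
  q <- qr(x)
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

# SS explained by the column space of H, in trace form
ss_hat <- function(h, g) sum(h * g)

# type III partition: SS(term | all other terms)
ss_partition_gower <- function(g, x, assign, term_ids) {
  h_full <- hat_matrix(x)
  rank_full <- qr(x)$rank
  reds <- lapply(term_ids, function(i) {
    xr <- x[, assign != i, drop = FALSE]
    list(h = hat_matrix(xr), rank = qr(xr)$rank)
  })
  list(
    h_full = h_full, rank_full = rank_full, reds = reds,
    ss = vapply(reds, function(r) ss_hat(h_full, g) - ss_hat(r$h, g), 1),
    df = vapply(reds, function(r) rank_full - r$rank, 1),
    ss_res = sum(diag(g)) - ss_hat(h_full, g),
    df_res = nrow(g) - rank_full,
    ss_total = sum(diag(g))
  )
}

# same partition computed from the raw response (tr(H Yc Yc')); used as the
# second code path for the Gower-identity check
ss_partition_response <- function(y, x, assign, term_ids) {
  yc <- scale(y, center = TRUE, scale = FALSE)
  g <- tcrossprod(yc)
  ss_partition_gower(g, x, assign, term_ids)
}

multinom_count <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# distinct relabelings of a single factor: multinomial count divided by the
# permutations of equal-sized groups (swapping whole groups of the same size
# leaves every statistic unchanged)
unique_relabelings <- function(sizes) {
  sym <- prod(factorial(table(sizes)))
  round(multinom_count(sizes) / sym)
}

# all distinct assignments of observations to design cells with fixed sizes;
# returns a matrix with one permutation (index vector) per column
enum_assignments <- function(cells) {
  cells <- as.integer(factor(cells))
  n <- length(cells)
  k <- max(cells)
  slots <- split(seq_len(n), cells) # design positions per cell
  rec <- function(avail, cell) {
    if (cell > k) return(list(integer(0)))
    take <- length(slots[[cell]])
    picks <- utils::combn(avail, take, simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- rec(setdiff(avail, p), cell + 1)
      out <- c(out, lapply(rest, function(r) c(p, r)))
    }
    out
  }
  combos <- rec(seq_len(n), 1)
  vapply(combos, function(members) {
    p <- integer(n)
    start <- 1
    for (cell in seq_len(k)) {
      take <- length(slots[[cell]])
      p[slots[[cell]]] <- members[start:(start + take - 1)]
      start <- start + take
    }
    p
  }, integer(n))
}

#' PERMANOVA on Euclidean distances with type III sums of squares
#'
#' Permutational (multivariate) analysis of variance for crossed one- or
#' two-factor designs. Sums of squares are partitioned in the
#' Gower-centred trace form with type III (partial) sums of squares, so
#' each term is tested conditional on all others. Significance is assessed
#' by unrestricted permutation of the raw observations; when the number of
#' distinct relabelings is smaller than `permutations` every distinct
#' relabeling is enumerated exactly. A parametric Monte Carlo p-value
#' (`p_mc`) from the F(df_term, df_residual) reference distribution is
#' reported alongside, as the asymptotic stand-in used for designs too
#' small for informative permutation.
#'
#' For a univariate response the pseudo-F equals the classical ANOVA F.
#'
#' @param data A data frame with the factors and response columns.
#' @param response <[`tidy-select`][dplyr::dplyr_tidy_select]> columns
#'   forming the (possibly multivariate) numeric response.
#' @param formula Right-hand-side formula in the factors, e.g.
#'   `~ species * food_source`.
#' @param permutations Number of random permutations when exhaustive
#'   enumeration is not feasible (default 9999).
#' @param seed Optional integer seed for the permutation draw.
#' @param distance Optional `dist` object; when supplied the analysis runs
#'   on it directly and `response` is ignored (with Euclidean distance the
#'   two routes agree by the Gower identity).
#' @return An object of class `spongeflux_permanova` with [tidy()] and
#'   [glance()] methods. `tidy()` gives one row per term: `df`, `ss`,
#'   `pseudo_f`, `p_perm`, `p_mc`, `unique_permutations`, `method`
#'   (`"enumerated"` or `"sampled"`).
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 4), y = rnorm(8))
#' tidy(permanova(d, y, ~ g, permutations = 999, seed = 1))
#' @export
permanova <- function(data, response, formula, permutations = 9999,
                      seed = NULL, distance = NULL) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  for (v in vars) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2) {
      abort(paste0("Factor `", v, "` has fewer than 2 levels."),
        class = "spongeflux_error_design")
    }
  }
  trm <- terms(formula)
  labels <- attr(trm, "term.labels")
  contr <- setNames(replicate(length(vars), stats::contr.sum, simplify = FALSE), vars)
  x <- model.matrix(formula, data, contrasts.arg = contr)
  assign <- attr(x, "assign")
  term_ids <- seq_along(labels)

  if (is.null(distance)) {
    y <- as.matrix(dplyr::select(as_tibble(data), {{ response }}))
    storage.mode(y) <- "double"
    if (anyNA(y)) abort("Missing values in the response.",
      class = "spongeflux_error_domain")
    g <- gower_matrix(dist(y))
  } else {
    g <- gower_matrix(distance)
  }
  n <- nrow(g)
  part <- ss_partition_gower(g, x, assign, term_ids)
  degenerate <- part$ss_total < 1e-12 * max(1, n)
  zero_df <- part$df == 0 # term aliased in a non-crossed design
  if (any(zero_df)) {
    warn(paste0("Term(s) not estimable (0 df) in this design: ",
      paste(labels[zero_df], collapse = ", ")))
  }
  f_obs <- if (degenerate) rep(0, length(term_ids)) else {
    suppressWarnings((part$ss / part$df) / (part$ss_res / part$df_res))
  }

  cells <- interaction(data[vars], drop = TRUE)
  n_assign <- multinom_count(as.vector(table(cells)))
  uniq <- if (length(vars) == 1) {
    unique_relabelings(as.vector(table(cells)))
  } else {
    n_assign
  }

  stat_for <- function(p) {
    gp <- g[p, p]
    ss <- vapply(seq_along(term_ids), function(i) {
      ss_hat(part$h_full, gp) - ss_hat(part$reds[[i]]$h, gp)
    }, 1)
    ss_res <- sum(diag(g)) - ss_hat(part$h_full, gp)
    (ss / part$df) / (ss_res / part$df_res)
  }

  if (degenerate) {
    p_perm <- rep(1, length(term_ids))
    method <- "degenerate"
    null_f <- NULL
  } else if (n_assign <= permutations) {
    perms <- enum_assignments(as.integer(cells))
    null_f <- apply(perms, 2, stat_for)
    null_f <- matrix(null_f, nrow = length(term_ids))
    tol <- 1e-8 * pmax(1, abs(f_obs))
    p_perm <- rowMeans(null_f >= f_obs - tol)
    method <- "enumerated"
  } else {
    draw <- function() {
      null_f <- replicate(permutations, stat_for(sample.int(n)))
      matrix(null_f, nrow = length(term_ids))
    }
    null_f <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    tol <- 1e-8 * pmax(1, abs(f_obs))
    p_perm <- (rowSums(null_f >= f_obs - tol) + 1) / (permutations + 1)
    method <- "sampled"
  }

  p_mc <- if (degenerate) rep(1, length(term_ids)) else {
    suppressWarnings(pf(f_obs, part$df, part$df_res, lower.tail = FALSE))
  }
  f_obs[zero_df] <- NA_real_
  p_perm[zero_df] <- NA_real_
  p_mc[zero_df] <- NA_real_

  out <- list(
    terms = tibble(
      term = labels,
      df = part$df,
      ss = part$ss,
      pseudo_f = f_obs,
      p_perm = p_perm,
      p_mc = p_mc,
      unique_permutations = rep(uniq, length(labels)),
      method = rep(method, length(labels))
    ),
    residual = tibble(df = part$df_res, ss = part$ss_res),
    ss_total = part$ss_total,
    n = n,
    formula = formula,
    permutations = permutations,
    null_f = null_f
  )
  class(out) <- "spongeflux_permanova"
  out
}

#' @export
print.spongeflux_permanova <- function(x, ...) {
  cat("PERMANOVA (Euclidean distance, type III SS),",
    format(x$formula), "\n")
  cat("n =", x$n, "; residual df =", x$residual$df, "\n")
  print(x$terms, ...)
  invisible(x)
}

#' @rdname permanova
#' @param x A `spongeflux_permanova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spongeflux_permanova <- function(x, ...) x$terms

#' @rdname permanova
#' @exportS3Method generics::glance
glance.spongeflux_permanova <- function(x, ...) {
  tibble(
    n = x$n, ss_total = x$ss_total,
    df_residual = x$residual$df, ss_residual = x$residual$ss,
    permutations = x$permutations
  )
}

#' Histogram of the permutation null distribution
#'
#' @param object A `spongeflux_permanova` fit (with a non-degenerate
#'   permutation distribution).
#' @param term Which term to plot (default first).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spongeflux_permanova <- function(object, term = 1, ...) {
  if (is.null(object$null_f)) {
    abort("No permutation distribution stored (degenerate fit).")
  }
  df <- tibble(f = object$null_f[term, ])
  obs <- object$terms$pseudo_f[term]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = obs, colour = "red") +
    ggplot2::labs(
      x = "pseudo-F under permutation",
      y = "count",
      title = paste0("Permutation null, term: ", object$terms$term[term])
    )
}

#' Pairwise PERMANOVA comparisons
#'
#' PRIMER-style post hoc pairwise tests after a significant factor: for
#' each pair of levels a two-level one-factor PERMANOVA is fitted on the
#' sub-design, the pairwise statistic is t = sqrt(pseudo-F), and the Monte
#' Carlo p-value comes from the t distribution with the residual degrees of
#' freedom. Distinct relabelings are enumerated exactly when few.
#'
#' @inheritParams permanova
#' @param factor_name Name (string) of the factor column to compare.
#' @return Tibble with one row per pair: `level_1`, `level_2`, `df`, `t`,
#'   `p_perm`, `p_mc`, `unique_permutations`, `method`.
#' @export
pairwise_permanova <- function(data, response, factor_name,
                               permutations = 9999, seed = NULL) {
  data <- as.data.frame(data)
  lv <- unique(as.character(data[[factor_name]]))
  pairs <- utils::combn(sort(lv), 2, simplify = FALSE)
  res <- purrr::map(pairs, function(pr) {
    sub <- data[data[[factor_name]] %in% pr, , drop = FALSE]
    sizes <- as.vector(table(sub[[factor_name]])[pr])
    if (any(sizes < 2)) {
      warn(paste0("Skipping pair ", pr[1], " vs ", pr[2],
        ": fewer than 2 observations per level."))
      return(NULL)
    }
    sub$.pair_factor <- sub[[factor_name]]
    fit <- permanova(sub, {{ response }}, ~.pair_factor,
      permutations = permutations, seed = seed)
    tt <- fit$terms
    df_res <- fit$residual$df
    t_stat <- sqrt(max(tt$pseudo_f, 0))
    tibble(
      level_1 = pr[1], level_2 = pr[2],
      df = df_res, t = t_stat,
      p_perm = tt$p_perm,
      p_mc = if (tt$method == "degenerate") 1 else
        2 * pt(abs(t_stat), df_res, lower.tail = FALSE),
      unique_permutations = tt$unique_permutations,
      method = tt$method
    )
  })
  bind_rows(res)
}

#' Welch's two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (unequal variances, two-sided)
#' returning a tidy one-row tibble; degenerate zero-variance samples are
#' guarded: equal constant samples give t = 0, p = 1.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return Tibble with `t`, `df` (Welch-Satterthwaite), `p_value`,
#'   `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Each sample needs at least 2 observations.",
      class = "spongeflux_error_design")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble(
      t = if (same) 0 else Inf * sign(mean(x) - mean(y)),
      df = length(x) + length(y) - 2,
      p_value = if (same) 1 else 0,
      mean_x = mean(x), mean_y = mean(y)
    ))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_x = mean(x), mean_y = mean(y)
  )
}
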