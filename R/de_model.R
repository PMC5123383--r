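#' Fit the fold-change significance envelope
#'
#' In an MA-style scatter of log2 fold change against mean expression,
#' technical variability draws a rhomboid cloud whose left border widens
#' as counts shrink. The envelope is estimated by binning genes on
#' log-spaced mean-expression bins, extracting per bin the point attaining
#' the `q`-th quantile of |log2 FC| (the quantile is paired with that
#' point's own mean expression, which avoids the bias a bin-center pairing
#' would incur from the within-bin spread of means), and fitting the
#' decreasing hyperbola `t(m) = a / (m + c) + b` (`a > 0`, `b, c >= 0`) to
#' the boundary points by least squares on `log t`. The symmetric pair
#' `+-t(m)` acts as the fuzzy threshold for fold-change significance: the
#' membership surfaces built from it cross 0.5 exactly at `+-t(m)`.
#'
#' If the hyperbola fit fails or is degenerate the envelope falls back,
#' with a warning, to a monotone (isotonic, nonincreasing) interpolation
#' of the boundary points.
#'
#' @param data A data frame of per-gene points.
#' @param mean_expr,log2fc Columns of `data` holding mean expression and
#'   log2 fold change (tidy-eval; defaults `mean_expr`, `log2fc`).
#'   Infinite fold changes and nonpositive means are excluded from the fit.
#' @param q Quantile of |log2 FC| defining the per-bin boundary.
#' @param min_m Minimum mean expression for a point to enter the fit.
#' @param n_bins Number of log-spaced bins.
#' @param min_points Minimum number of usable points.
#' @param t_floor Lower floor on the threshold, keeping the membership
#'   surfaces well-defined when the envelope collapses (e.g. identical
#'   samples), in log2 units.
#' @return An object of class `fc_threshold` with the fitted parameters;
#'   see [threshold()], [de_membership()], [membership_surfaces()].
#' @export
fit_fc_threshold <- function(data, mean_expr = mean_expr, log2fc = log2fc,
                             q = 0.99, min_m = 0, n_bins = 30,
                             min_points = 50, t_floor = 0.01) {
  m <- dplyr::pull(data, {{ mean_expr }})
  fc <- dplyr::pull(data, {{ log2fc }})
  ok <- is.finite(m) & is.finite(fc) & m > min_m & m > 0
  m <- m[ok]
  fc <- abs(fc[ok])
  if (length(m) < min_points) {
    stop("envelope fit needs at least ", min_points, " finite points above min_m (got ",
         length(m), ")", call. = FALSE)
  }

  model <- envelope_pass(m, fc, q, n_bins, t_floor)
  # one outlier-rejection pass: points far above the first envelope are
  # DE events, not technical variability, and must not inflate it
  keep <- fc <= 2 * threshold(model, m)
  if (any(!keep) && sum(keep) >= min_points) {
    model <- envelope_pass(m[keep], fc[keep], q, n_bins, t_floor)
    model$n_trimmed <- sum(!keep)
  } else {
    model$n_trimmed <- 0L
  }
  model$n_points <- length(m)
  model
}

# single envelope estimation pass: bin, extract boundary points, fit
envelope_pass <- function(m, fc, q, n_bins, t_floor) {
  # never ask for more bins than the data can fill with ~10 points each
  n_bins <- max(3L, min(n_bins, floor(length(m) / 10)))
  br <- exp(seq(log(min(m)), log(max(m)), length.out = n_bins + 1))
  bin <- findInterval(m, br, rightmost.closed = TRUE)
  pts <- purrr::map(split(tibble::tibble(m = m, a = fc), bin), function(d) {
    if (nrow(d) < 5) return(NULL)
    i <- order(d$a)[max(1L, ceiling(q * nrow(d)))]
    tibble::tibble(m = d$m[i], t = d$a[i])
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(m)

  model <- list(q = q, n_points = length(m), m_range = range(m),
                t_floor = t_floor, boundary = pts)
  fit <- NULL
  if (nrow(pts) >= 3 && any(pts$t > 0)) {
    fit <- tryCatch({
      fp <- pts[pts$t > 0, ]
      a0 <- stats::median(fp$t * fp$m)
      out <- minpack.lm::nls.lm(
        par = list(a = max(a0, 1e-6), b = max(min(fp$t) / 2, 1e-4), c = 1),
        fn = function(p) {
          # asymmetric log-scale loss: a boundary point above the fitted
          # curve (positive residual, under-coverage) weighs double, so
          # the curve envelops the cloud instead of bisecting it
          r <- log(fp$t) - log(p$a / (fp$m + p$c) + p$b)
          r * ifelse(r > 0, 2, 1)
        },
        lower = c(1e-9, 0, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
      if (out$info %in% c(0, 5) || out$par$a <= 0) NULL else out$par
    }, error = function(e) NULL)
  }
  if (!is.null(fit)) {
    model$type <- "hyperbola"
    model$a <- fit$a
    model$b <- fit$b
    model$c <- fit$c
  } else {
    warning("hyperbola fit unavailable or degenerate; ",
            "falling back to a monotone envelope", call. = FALSE)
    model$type <- "isotonic"
    model$a <- model$b <- model$c <- NA_real_
    if (nrow(pts) >= 2) {
      iso <- stats::isoreg(pts$m, -pts$t)
      model$boundary <- tibble::tibble(m = pts$m, t = pmax(-iso$yf, 0))
    } else if (nrow(pts) == 0) {
      model$boundary <- tibble::tibble(m = model$m_range, t = c(t_floor, t_floor))
    }
  }
  structure(model, class = "fc_threshold")
}

# a conservative envelope used by fuzzy_de() when the gene set is too
# small to fit: decays like 4/m at low counts and never drops below one
# log2 unit (the conventional two-fold cutoff); documented in the vignette
default_fc_threshold <- function(t_floor = 0.01) {
  structure(list(type = "hyperbola", a = 4, b = 1, c = 1, q = NA_real_,
                 n_points = 0L, m_range = c(0.1, 1e6), t_floor = t_floor,
                 boundary = tibble::tibble(m = double(), t = double())),
            class = "fc_threshold")
}

#' Evaluate the fold-change significance threshold
#'
#' The symmetric |log2 FC| envelope value `t(m)` at mean expression `m`;
#' `m` outside the fitted range is clamped to its endpoints and the
#' result is floored at the model's `t_floor`.
#'
#' @param model An `fc_threshold` model from [fit_fc_threshold()].
#' @param m Mean expression value(s).
#' @return Threshold value(s), strictly positive.
#' @export
threshold <- function(model, m) {
  stopifnot(inherits(model, "fc_threshold"))
  mc <- pmin(pmax(m, model$m_range[1]), model$m_range[2])
  t <- if (model$type == "hyperbola") {
    model$a / (mc + model$c) + model$b
  } else {
    stats::approx(model$boundary$m, model$boundary$t, xout = mc, rule = 2)$y
  }
  pmax(t, model$t_floor)
}

#' Membership degrees of the three differential-expression concepts
#'
#' For a gene at mean expression `m` with log2 fold change `fc`, the three
#' fuzzy DE concepts are evaluated as:
#' * same-expression: Gaussian `exp(-fc^2 / (2 sigma^2))` with
#'   `sigma = t(m) / sqrt(2 ln 2)`, so membership is 1 at `fc = 0` and 0.5
#'   at the threshold points `+-t(m)`;
#' * over-expression: increasing sigmoid `1 / (1 + exp(-s (fc - t(m))))`
#'   with steepness `s = ln(99) / t(m)`, crossing 0.5 at `t(m)` and worth
#'   0.01 at `fc = 0`;
#' * under-expression: the mirrored sigmoid.
#'
#' All three have infinite support, turning the crisp envelope into a
#' gradual boundary. Infinite `fc` values evaluate at the limit (Gaussian
#' 0, sigmoids 0 or 1).
#'
#' @param model An `fc_threshold` model.
#' @param m Mean expression value(s), recycled against `fc`.
#' @param fc Log2 fold-change value(s).
#' @return A tibble with columns `under`, `same`, `over` in \[0, 1\].
#' @export
de_membership <- function(model, m, fc) {
  t <- threshold(model, m)
  sigma <- t / sqrt(2 * log(2))
  same <- exp(-fc^2 / (2 * sigma^2))
  same[is.infinite(fc)] <- 0
  s <- log(99) / t
  over <- stats::plogis(s * (fc - t))
  under <- stats::plogis(s * (-fc - t))
  tibble::tibble(under = under, same = same, over = over)
}

#' Membership surfaces at a fixed mean expression
#'
#' Slices the three DE membership surfaces at mean expression `m`,
#' returning the three membership functions over log2 fold change plus the
#' threshold value where the sigmoids and the Gaussian cross 0.5.
#'
#' @param model An `fc_threshold` model.
#' @param m A single positive mean expression value.
#' @return A list with functions `under(fc)`, `same(fc)`, `over(fc)` and
#'   the numeric threshold `t`.
#' @export
membership_surfaces <- function(model, m) {
  if (!is.numeric(m) || length(m) != 1 || !is.finite(m) || m <= 0) {
    stop("`m` must be a single positive mean expression value", call. = FALSE)
  }
  force(model)
  list(
    under = function(fc) de_membership(model, m, fc)$under,
    same = function(fc) de_membership(model, m, fc)$same,
    over = function(fc) de_membership(model, m, fc)$over,
    t = threshold(model, m)
  )
}

#' Joint possibility relation of a gene's counts in two samples
#'
#' The Cartesian product of the case and control fuzzy counts under the
#' min t-norm: `relation(x, y) = min(case(x), control(y))`, the truncated
#' pyramid whose height at `(x, y)` is the possibility that the case has
#' `x` reads and the control `y` reads. Counts are assumed
#' non-interacting.
#'
#' @param case,control Length-4 numeric vectors `c(A, B, C, D)` of the two
#'   (normalized) trapezoids.
#' @return A vectorized function of `(x, y)` returning degrees in \[0, 1\].
#' @export
joint_relation <- function(case, control) {
  stopifnot(length(case) == 4, length(control) == 4)
  function(x, y) {
    pmin(trapezoid_membership(x, case[1], case[2], case[3], case[4]),
         trapezoid_membership(y, control[1], control[2], control[3], control[4]))
  }
}

# scalar fast path of de_membership() for the local polish
surf_value <- function(model, m, fc, surf) {
  t <- threshold(model, m)
  if (surf == "same") {
    if (is.infinite(fc)) return(0)
    return(exp(-fc^2 * log(2) / t^2))
  }
  s <- log(99) / t
  if (surf == "over") stats::plogis(s * (fc - t)) else stats::plogis(s * (-fc - t))
}

# Evaluation grid over one trapezoid's support: linear spacing plus a
# geometric refinement toward zero (where log2 fold change varies fastest
# per count unit) plus the exact knots, so core vertices are never
# approximated.
possibility_grid <- function(A, B, C, D, grid_n) {
  lo <- max(A - 1, 0)
  hi <- D + 1
  xs <- seq(lo, hi, length.out = grid_n)
  geo_lo <- max(lo, hi * 1e-3)
  if (geo_lo < hi) {
    xs <- c(xs, exp(seq(log(geo_lo), log(hi), length.out = grid_n)))
  }
  # extra resolution across the two membership shoulders, where the
  # relation changes fastest
  ns <- max(8L, grid_n %/% 2)
  if (B > lo) xs <- c(xs, seq(lo, B, length.out = ns))
  if (hi > C) xs <- c(xs, seq(C, hi, length.out = ns))
  sort(unique(c(xs, A, B, C, D, lo, hi)))
}

# sup-min intersection for one gene; trapezoids given as A,B,C,D scalars
de_possibility_one <- function(A1, B1, C1, D1, A2, B2, C2, D2, model, grid_n = 64) {
  if (A1 == D1 && A2 == D2) {
    # point counts: no multiread uncertainty, match the punctual fold
    # change directly against the three membership functions
    if (A1 == 0 && A2 == 0) {
      return(c(under = 0, same = 1, over = 0))
    }
    fc <- log2(A1 / A2) # may be +-Inf
    mem <- de_membership(model, (A1 + A2) / 2, fc)
    return(c(under = mem$under, same = mem$same, over = mem$over))
  }
  lo1 <- max(A1 - 1, 0); hi1 <- D1 + 1
  lo2 <- max(A2 - 1, 0); hi2 <- D2 + 1
  xs <- possibility_grid(A1, B1, C1, D1, grid_n)
  ys <- possibility_grid(A2, B2, C2, D2, grid_n)
  mx <- trapezoid_membership(xs, A1, B1, C1, D1)
  my <- trapezoid_membership(ys, A2, B2, C2, D2)
  rel <- outer(mx, my, pmin)
  fc <- log2(outer(xs, ys, "/"))
  fc[is.nan(fc)] <- 0 # the (0, 0) cell carries no evidence of change
  mm <- outer(xs, ys, function(x, y) (x + y) / 2)
  mem <- de_membership(model, as.vector(mm), as.vector(fc))
  r <- as.vector(rel)

  # the grid maximum is then polished by a continuous local search, so
  # optima sitting between grid lines (shoulder-shoulder crossings) are
  # found exactly rather than at grid resolution
  polish <- function(which_surf, start_val) {
    i <- which.max(pmin(r, mem[[which_surf]]))
    start <- c(xs[(i - 1) %% length(xs) + 1], ys[(i - 1) %/% length(xs) + 1])
    f <- function(p) {
      x <- p[1]; y <- p[2]
      if (x < lo1 || x > hi1 || y < lo2 || y > hi2) return(1)
      relv <- min(trapezoid_membership(x, A1, B1, C1, D1),
                  trapezoid_membership(y, A2, B2, C2, D2))
      fcv <- if (x == 0 && y == 0) 0 else log2(x / y)
      -min(relv, surf_value(model, (x + y) / 2, fcv, which_surf))
    }
    opt <- tryCatch(
      stats::optim(start, f, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-10)),
      error = function(e) list(value = -start_val)
    )
    max(start_val, -opt$value)
  }

  vals <- c(under = max(pmin(r, mem$under)),
            same = max(pmin(r, mem$same)),
            over = max(pmin(r, mem$over)))
  c(under = polish("under", vals[["under"]]),
    same = polish("same", vals[["same"]]),
    over = polish("over", vals[["over"]]))
}

#' Possibility of over-, same- and under-expression per gene
#'
#' Intersects each gene's joint count relation (the truncated pyramid of
#' [joint_relation()]) with the three membership surfaces by sup-min
#' composition: the possibility of each DE concept is the maximum over
#' the support of the minimum between the relation and the surface. The
#' surfaces are looked up at the arithmetic mean of the two grid
#' coordinates and at `fc = log2(x / y)`; cells with one zero coordinate
#' evaluate the surfaces at the infinite-fold-change limit. The sup is
#' approximated on a `grid_n` x `grid_n` grid that always contains the
#' trapezoid knots exactly, so core vertices are evaluated without
#' approximation and `max(under, same, over) >= 0.5` holds for every
#' valid gene. Genes whose counts are points in both conditions (no
#' multireads) are matched directly against the membership functions;
#' a gene with the zero point count in both conditions returns
#' `(under, same, over) = (0, 1, 0)` by convention.
#'
#' @param case,control Fuzzy count tables of the two conditions
#'   (normalized). Genes missing from one side get the zero trapezoid.
#' @param model An `fc_threshold` model from [fit_fc_threshold()].
#' @param grid_n Grid resolution per axis.
#' @return A tibble `gene, p_under, p_same, p_over` with values in
#'   \[0, 1\].
#' @export
de_possibility <- function(case, control, model, grid_n = 64) {
  stopifnot(inherits(model, "fc_threshold"))
  both <- stack_pair(check_count_table(case), check_count_table(control))
  poss <- purrr::pmap(
    both[c("A1", "B1", "C1", "D1", "A2", "B2", "C2", "D2")],
    function(A1, B1, C1, D1, A2, B2, C2, D2) {
      de_possibility_one(A1, B1, C1, D1, A2, B2, C2, D2, model, grid_n)
    }
  )
  tibble::tibble(
    gene = both$gene,
    p_under = purrr::map_dbl(poss, "under"),
    p_same = purrr::map_dbl(poss, "same"),
    p_over = purrr::map_dbl(poss, "over")
  )
}

#' @export
print.fc_threshold <- function(x, ...) {
  cat("<fc_threshold> fold-change significance envelope\n")
  if (x$type == "hyperbola") {
    cat(sprintf("  t(m) = %.4g / (m + %.4g) + %.4g\n", x$a, x$c, x$b))
  } else {
    cat("  monotone (isotonic) envelope on", nrow(x$boundary), "boundary points\n")
  }
  cat(sprintf("  quantile q = %s, fitted on %d genes, m in [%.4g, %.4g], floor %.3g\n",
              format(x$q), x$n_points, x$m_range[1], x$m_range[2], x$t_floor))
  invisible(x)
}

#' Tidy a fitted fold-change envelope
#'
#' @param x An `fc_threshold` model.
#' @param ... Unused.
#' @return `tidy()`: one row per hyperbola parameter; `glance()`: a
#'   one-row model summary.
#' @method tidy fc_threshold
#' @export
tidy.fc_threshold <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @rdname tidy.fc_threshold
#' @method glance fc_threshold
#' @export
glance.fc_threshold <- function(x, ...) {
  tibble::tibble(type = x$type, q = x$q, n_points = x$n_points,
                 m_lo = x$m_range[1], m_hi = x$m_range[2],
                 t_floor = x$t_floor)
}

#' Serialize a fitted envelope as JSON
#'
#' Writes the model parameters (family, a, b, c, quantile, fitted range,
#' boundary points) as a sidecar JSON file for reproducibility.
#'
#' @param model An `fc_threshold` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(model, path) {
  stopifnot(inherits(model, "fc_threshold"))
  jsonlite::write_json(
    list(type = model$type, a = model$a, b = model$b, c = model$c,
         q = model$q, n_points = model$n_points,
         m_range = model$m_range, t_floor = model$t_floor,
         boundary = model$boundary),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
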