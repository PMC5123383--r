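# a simple fixed envelope for membership/possibility tests
fixed_model <- function(a = 4, b = 0.2, cc = 1) {
  structure(list(type = "hyperbola", a = a, b = b, c = cc, q = 0.99,
                 n_points = 100L, m_range = c(0.5, 1e4), t_floor = 0.01,
                 boundary = tibble::tibble(m = double(), t = double())),
            class = "fc_threshold")
}

trap_tbl <- function(v, gene = "g") {
  v <- unname(v)
  tibble::tibble(gene = gene, A = v[1], B = v[2], C = v[3], D = v[4])
}

test_that("a known 4/m envelope is recovered within 5%", {
  withr::local_seed(101)
  n <- 3000
  m <- exp(runif(n, log(0.5), log(200)))
  fc <- runif(n, -1, 1) * 4 / m
  model <- fit_fc_threshold(tibble::tibble(mean_expr = m, log2fc = fc))
  expect_s3_class(model, "fc_threshold")
  expect_equal(model$type, "hyperbola")
  for (mm in c(1, 10, 100)) {
    expect_lt(abs(threshold(model, mm) - 4 / mm) / (4 / mm), 0.05)
  }
  # decreasing over the fitted range
  grid <- exp(seq(log(0.6), log(190), length.out = 50))
  expect_true(all(diff(threshold(model, grid)) <= 0))
  expect_true(all(threshold(model, grid) > 0))
})

test_that("the fitted envelope contains about the target fraction of points", {
  withr::local_seed(102)
  n <- 4000
  m <- exp(runif(n, log(1), log(500)))
  fc <- rnorm(n, 0, 1.2 / sqrt(m)) # technical-replicate-like noise
  model <- fit_fc_threshold(tibble::tibble(mean_expr = m, log2fc = fc), q = 0.99)
  inside <- mean(abs(fc) <= threshold(model, m))
  expect_gte(inside, 0.99 - 0.02)
})

test_that("identical samples collapse the envelope and flag every gene as same", {
  withr::local_seed(103)
  m <- exp(runif(200, log(5), log(500)))
  suppressWarnings(
    model <- fit_fc_threshold(tibble::tibble(mean_expr = m, log2fc = rep(0, 200)))
  )
  expect_lte(threshold(model, 50), 0.05)
  mem <- de_membership(model, 50, 0)
  expect_equal(mem$same, 1)
  expect_lte(mem$over, 0.01 + 1e-9)
})

test_that("too few usable points is an error", {
  expect_error(
    fit_fc_threshold(tibble::tibble(mean_expr = 1:10, log2fc = rnorm(10))),
    "at least 50"
  )
  # infinite fold changes are excluded before the count
  d <- tibble::tibble(mean_expr = rep(10, 60), log2fc = c(rep(Inf, 30), rnorm(30)))
  expect_error(fit_fc_threshold(d), "at least 50")
})

test_that("membership surfaces cross the threshold points at 0.5", {
  model <- fixed_model()
  for (m in c(1, 20, 300)) {
    t <- threshold(model, m)
    surf <- membership_surfaces(model, m)
    expect_equal(surf$same(0), 1)
    expect_equal(surf$same(t), 0.5)
    expect_equal(surf$same(-t), 0.5)
    expect_equal(surf$over(t), 0.5)
    expect_equal(surf$under(-t), 0.5)
    expect_gt(surf$over(3 * t), 0.99)
    expect_lt(surf$over(0), 0.011)
    # infinite fold change evaluates at the limit
    expect_equal(surf$same(Inf), 0)
    expect_equal(surf$over(Inf), 1)
    expect_equal(surf$over(-Inf), 0)
  }
  expect_error(membership_surfaces(model, 0), "positive")
  expect_error(membership_surfaces(model, -3), "positive")
})

test_that("the joint relation is the min t-norm of the two trapezoids", {
  rel <- joint_relation(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(rel(5, 2.5), 1)            # both cores
  expect_equal(rel(1, 2.5), 0)            # outside the case support
  expect_equal(rel(3, 2.5), 2 / 3)        # case shoulder, control core
  expect_equal(rel(5, 4.5), 0.25)         # control shoulder: (4.5 - 5) / (3 - 5)
  expect_equal(rel(3, 4.5), min(2 / 3, 0.25))
})

test_that("point counts match direct membership evaluation exactly", {
  model <- fixed_model()
  withr::local_seed(104)
  for (i in 1:15) {
    x <- sample(1:400, 1)
    y <- sample(1:400, 1)
    got <- de_possibility(trap_tbl(rep(x, 4)), trap_tbl(rep(y, 4)), model)
    mem <- de_membership(model, (x + y) / 2, log2(x / y))
    expect_equal(got$p_under, mem$under, tolerance = 1e-9)
    expect_equal(got$p_same, mem$same, tolerance = 1e-9)
    expect_equal(got$p_over, mem$over, tolerance = 1e-9)
  }
  # zero against zero: no evidence of change, by convention
  got <- de_possibility(trap_tbl(rep(0, 4)), trap_tbl(rep(0, 4)), model)
  expect_equal(unlist(got[c("p_under", "p_same", "p_over")]),
               c(p_under = 0, p_same = 1, p_over = 0))
  # zero against a real count: an infinite fold change
  got <- de_possibility(trap_tbl(rep(60, 4)), trap_tbl(rep(0, 4)), model)
  expect_equal(got$p_over, 1)
  expect_equal(got$p_same, 0)
})

test_that("a point exactly on the envelope is half over, half same", {
  model <- fixed_model()
  y0 <- 40
  f <- function(x) log2(x / y0) - threshold(model, (x + y0) / 2)
  x0 <- uniroot(f, c(y0, 16 * y0), tol = 1e-12)$root
  got <- de_possibility(trap_tbl(rep(x0, 4)), trap_tbl(rep(y0, 4)), model)
  expect_equal(got$p_over, 0.5, tolerance = 1e-6)
  expect_equal(got$p_same, 0.5, tolerance = 1e-6)
})

test_that("identical fuzzy counts give same-expression possibility 1", {
  model <- fixed_model()
  withr::local_seed(105)
  for (i in 1:10) {
    tr <- random_trapezoid()
    got <- de_possibility(tr, tr, model)
    expect_equal(got$p_same, 1)
  }
})

test_that("swapping case and control swaps under and over and keeps same", {
  model <- fixed_model()
  withr::local_seed(106)
  for (i in 1:10) {
    a <- random_trapezoid()
    b <- random_trapezoid()
    fwd <- de_possibility(a, b, model)
    rev <- de_possibility(b, a, model)
    expect_equal(fwd$p_over, rev$p_under, tolerance = 0.01)
    expect_equal(fwd$p_under, rev$p_over, tolerance = 0.01)
    expect_equal(fwd$p_same, rev$p_same, tolerance = 0.01)
  }
})

test_that("widening a trapezoid never decreases any possibility", {
  model <- fixed_model()
  withr::local_seed(107)
  for (i in 1:10) {
    a <- unlist(random_trapezoid()[c("A", "B", "C", "D")])
    b <- random_trapezoid()
    base <- de_possibility(trap_tbl(a), b, model)
    wide <- de_possibility(trap_tbl(c(max(a[1] - 3, 0), max(a[2] - 1, a[1] - 3, 0),
                                      a[3] + 1, a[4] + 4)), b, model)
    expect_gte(wide$p_under, base$p_under - 0.01)
    expect_gte(wide$p_same, base$p_same - 0.01)
    expect_gte(wide$p_over, base$p_over - 0.01)
  }
})

test_that("one of the three possibilities always reaches 0.5", {
  model <- fixed_model()
  withr::local_seed(108)
  for (i in 1:20) {
    got <- de_possibility(random_trapezoid(), random_trapezoid(), model)
    expect_gte(max(got$p_under, got$p_same, got$p_over), 0.5)
  }
})

test_that("the sup-min grid is converged at the default resolution", {
  model <- fixed_model()
  withr::local_seed(109)
  for (i in 1:8) {
    a <- random_trapezoid()
    b <- random_trapezoid()
    g1 <- de_possibility(a, b, model, grid_n = 64)
    g2 <- de_possibility(a, b, model, grid_n = 128)
    expect_lt(max(abs(unlist(g1[-1]) - unlist(g2[-1]))), 0.01)
  }
})

test_that("the envelope serializes to JSON and tidies", {
  model <- fixed_model()
  td <- tidy(model)
  expect_equal(td$term, c("a", "b", "c"))
  expect_equal(td$estimate, c(4, 0.2, 1))
  g <- glance(model)
  expect_equal(g$type, "hyperbola")
  f <- withr::local_tempfile(fileext = ".json")
  write_threshold_json(model, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$a, 4)
  expect_equal(back$m_range, c(0.5, 1e4))
})
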