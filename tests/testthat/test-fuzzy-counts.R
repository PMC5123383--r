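test_that("the worked-example trapezoids match the hand counts", {
  tab <- toy_mappings()
  g1 <- compute_abcd(tab, "gene-1")
  # one unique read; two strict best matches; three best matches
  # (read-3 ties on gene-2); five reads touch the gene
  expect_equal(unlist(g1[c("A", "B", "C", "D")]),
               c(A = 1, B = 2, C = 3, D = 5))
  # gene-3: no unique read, read-4 is a strict best, only read-2 and
  # read-4 carry records on it (verified against the exact enumeration)
  g3 <- compute_abcd(tab, "gene-3")
  expect_equal(unlist(g3[c("A", "B", "C", "D")]),
               c(A = 0, B = 1, C = 1, D = 2))
})

test_that("unique perfect hits collapse the trapezoid to a point", {
  tab <- tibble::tibble(read_id = paste0("r", 1:7),
                        reference_id = "g1", possibility = 1)
  got <- compute_abcd(tab, "g1")
  expect_equal(unlist(got[c("A", "B", "C", "D")]),
               c(A = 7, B = 7, C = 7, D = 7))
  # absent gene: the zero trapezoid, not an error
  zero <- compute_abcd(tab, "nope")
  expect_equal(unlist(zero[c("A", "B", "C", "D", "centroid")]),
               c(A = 0, B = 0, C = 0, D = 0, centroid = 0))
})

test_that("the exact discrete distribution reproduces the worked example", {
  got <- count_possibility(toy_mappings(), "gene-1")
  expect_equal(got$count, 0:5)
  expect_equal(got$possibility, c(0, 0.792, 1, 1, 0.864, 0.76))

  g3 <- count_possibility(toy_mappings(), "gene-3")
  expect_equal(g3$possibility, c(0.873, 1, 0.76))

  one <- count_possibility(
    tibble::tibble(read_id = "r1", reference_id = "g1", possibility = 1), "g1")
  expect_equal(one$possibility, c(0, 1))
})

test_that("the discrete distribution enumeration refuses oversized genes", {
  tab <- tibble::tibble(read_id = paste0("r", 1:25),
                        reference_id = "g1", possibility = 1)
  expect_error(count_possibility(tab, "g1", max_reads = 20), "trapezoid")
})

test_that("trapezoid bounds agree with the exact enumeration on random tables", {
  withr::local_seed(42)
  for (i in 1:25) {
    tab <- random_mapping_table(n_reads = sample(3:10, 1), n_genes = sample(2:5, 1))
    cnt <- fuzzy_counts(tab)
    for (g in cnt$gene) {
      d <- count_possibility(tab, g)
      row <- cnt[cnt$gene == g, ]
      support <- d$count[d$possibility > 0]
      plateau <- d$count[d$possibility == 1]
      expect_equal(range(support), c(row$A, row$D))
      expect_equal(range(plateau), c(row$B, row$C))
      # monotone up on [A, B], down on [C, D]
      up <- d$possibility[d$count >= row$A & d$count <= row$B]
      down <- d$possibility[d$count >= row$C & d$count <= row$D]
      expect_true(all(diff(up) >= 0))
      expect_true(all(diff(down) <= 0))
    }
  }
})

test_that("centroids conserve the read total and sit inside the support", {
  tab <- toy_mappings()
  cnt <- fuzzy_counts(tab)
  expect_equal(sum(cnt$centroid), 5, tolerance = 1e-12)
  # hand sum for gene-1: each read contributes pi / (sum of its pis)
  exp_g1 <- 1 + 1 / (1 + 0.792 + 0.76) + 1 / 2 +
    0.864 / (0.864 + 0.873 + 1) + 0.76 / (0.76 + 1)
  expect_equal(cnt$centroid[cnt$gene == "gene-1"], exp_g1)

  withr::local_seed(7)
  for (i in 1:10) {
    tab <- random_mapping_table(12, 4)
    cnt <- fuzzy_counts(tab)
    expect_equal(sum(cnt$centroid), length(unique(tab$read_id)), tolerance = 1e-9)
    expect_true(all(cnt$centroid >= cnt$A - 1e-12 & cnt$centroid <= cnt$D + 1e-12))
  }
})

test_that("genes untouched by multireads have point trapezoids", {
  withr::local_seed(11)
  tab <- random_mapping_table(15, 4)
  cnt <- fuzzy_counts(tab)
  multi <- tab$read_id[duplicated(tab$read_id)]
  touched <- unique(tab$reference_id[tab$read_id %in% multi])
  pure <- cnt[!cnt$gene %in% touched, ]
  expect_true(all(pure$A == pure$D))
})

test_that("technical merging is the componentwise sum", {
  t1 <- tibble::tibble(gene = "g", A = 1, B = 2, C = 3, D = 5)
  t2 <- tibble::tibble(gene = "g", A = 0, B = 1, C = 1, D = 3)
  zz <- tibble::tibble(gene = "g", A = 0, B = 0, C = 0, D = 0)
  p2 <- tibble::tibble(gene = "g", A = 2, B = 2, C = 2, D = 2)

  expect_equal(merge_technical(t1, zz), t1)
  expect_equal(unlist(merge_technical(t1, t1)[c("A", "B", "C", "D")]),
               c(A = 2, B = 4, C = 6, D = 10))
  expect_equal(unlist(merge_technical(t2, p2)[c("A", "B", "C", "D")]),
               c(A = 2, B = 3, C = 3, D = 5))
  # commutative and associative
  expect_equal(merge_technical(t1, t2), merge_technical(t2, t1))
  expect_equal(merge_technical(merge_technical(t1, t2), p2),
               merge_technical(t1, merge_technical(t2, p2)))
})

test_that("biological merging is the idempotent widening envelope", {
  t1 <- tibble::tibble(gene = "g", A = 1, B = 2, C = 3, D = 5)
  t2 <- tibble::tibble(gene = "g", A = 4, B = 6, C = 7, D = 9)
  zz <- tibble::tibble(gene = "g", A = 0, B = 0, C = 0, D = 0)
  p3 <- tibble::tibble(gene = "g", A = 3, B = 3, C = 3, D = 3)

  expect_equal(merge_biological(t1, t1), t1)
  expect_equal(unlist(merge_biological(t1, t2)[c("A", "B", "C", "D")]),
               c(A = 1, B = 2, C = 7, D = 9))
  # disjoint replicates: intermediate counts become fully possible
  expect_equal(unlist(merge_biological(zz, p3)[c("A", "B", "C", "D")]),
               c(A = 0, B = 0, C = 3, D = 3))
  expect_equal(merge_biological(t1, t2), merge_biological(t2, t1))
  expect_equal(merge_biological(merge_biological(t1, t2), p3),
               merge_biological(t1, merge_biological(t2, p3)))
  # widening: the merged support contains each input support
  withr::local_seed(5)
  for (i in 1:20) {
    a <- random_trapezoid()
    b <- random_trapezoid()
    m <- merge_biological(a, b)
    expect_lte(m$A, min(a$A, b$A))
    expect_gte(m$D, max(a$D, b$D))
  }
})

test_that("merging aligns gene sets, filling absences with the zero trapezoid", {
  t1 <- tibble::tibble(gene = c("g1", "g2"), A = c(1, 2), B = c(1, 2),
                       C = c(1, 2), D = c(1, 2))
  t2 <- tibble::tibble(gene = "g2", A = 4, B = 4, C = 4, D = 4)
  tech <- merge_technical(t1, t2)
  expect_equal(tech$A[tech$gene == "g1"], 1)
  expect_equal(tech$A[tech$gene == "g2"], 6)
  bio <- merge_biological(t1, t2)
  expect_equal(unlist(bio[bio$gene == "g1", c("A", "B", "C", "D")]),
               c(A = 0, B = 0, C = 1, D = 1))
})

test_that("trapezoid membership follows the one-count support extension", {
  # Tr[2,4,6,8]: zero at/below 1 and at/above 9, one on [4, 6]
  expect_equal(trapezoid_membership(c(1, 2, 3, 4, 5, 6, 7, 9), 2, 4, 6, 8),
               c(0, 1 / 3, 2 / 3, 1, 1, 1, 2 / 3, 0))
  # membership never leaks to negative counts
  expect_equal(trapezoid_membership(-0.5, 0, 0, 0, 0), 0)
  expect_equal(trapezoid_membership(0, 0, 0, 2, 2), 1)
})
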