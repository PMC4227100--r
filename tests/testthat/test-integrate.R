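make_model <- function(la, lb, gap = NULL) {
  ids <- paste0("S", seq_along(la))
  a <- cluster_assignment("mRNA", ids, la, "kmeans")
  b <- cluster_assignment("miRNA", ids, lb, "kmeans")
  p <- cross_tabulate(a, b)
  if (!is.null(gap)) p <- layout_parallel_sets(p, gap) else p
}

test_that("cross_tabulate counts contingency cells with member IDs", {
  p <- make_model(c(1, 1, 2, 2, 2), c(1, 2, 1, 2, 2))
  expect_equal(p$ribbons$count, c(1L, 1L, 1L, 2L))
  expect_equal(p$ribbons$label_a, c(1L, 1L, 2L, 2L))
  expect_equal(p$ribbons$label_b, c(1L, 2L, 1L, 2L))
  expect_equal(p$ribbons$members[[4]], c("S4", "S5"))

  ident <- make_model(c(1, 2, 3, 1, 2, 3), c(1, 2, 3, 1, 2, 3))
  expect_equal(nrow(ident$ribbons), 3)
  expect_true(all(ident$ribbons$label_a == ident$ribbons$label_b))

  a <- cluster_assignment("x", c("A", "B"), c(1, 2), "kmeans")
  b <- cluster_assignment("y", c("B", "A"), c(1, 2), "kmeans")
  expect_error(cross_tabulate(a, b), "align")
})

test_that("cross_tabulate is symmetric up to transposition and conserves n", {
  set.seed(77)
  la <- sample.int(3, 40, replace = TRUE)
  lb <- sample.int(2, 40, replace = TRUE)
  la <- canonical_labels(la); lb <- canonical_labels(lb)
  p <- make_model(la, lb)
  q <- make_model(lb, la)
  expect_equal(sum(p$ribbons$count), 40)
  key_p <- paste(p$ribbons$label_a, p$ribbons$label_b)
  key_q <- paste(q$ribbons$label_b, q$ribbons$label_a)
  expect_setequal(key_p, key_q)
  expect_equal(p$ribbons$count[order(key_p)], q$ribbons$count[order(key_q)])
})

test_that("independent random labels give near-multinomial ribbon counts", {
  set.seed(123)
  n <- 10000
  la <- canonical_labels(sample.int(3, n, replace = TRUE))
  lb <- canonical_labels(sample.int(3, n, replace = TRUE))
  p <- make_model(la, lb)
  expect_equal(nrow(p$ribbons), 9)
  mu <- n / 9
  sigma <- sqrt(n * (1 / 9) * (8 / 9))
  expect_true(all(abs(p$ribbons$count - mu) < 4 * sigma))
})

test_that("layout geometry is proportional and sums to the axis length", {
  p <- make_model(rep(1:2, c(50, 50)), rep(1:2, 50), gap = 0)
  expect_equal(p$blocks[[1]]$height, c(0.5, 0.5))
  expect_equal(p$blocks[[1]]$y, c(0, 0.5))

  p2 <- make_model(rep(1:2, c(30, 70)), rep(1, 100) + rep(0:1, 50), gap = 0.1)
  expect_equal(p2$blocks[[1]]$height, c(0.27, 0.63), tolerance = 1e-9)
  for (ax in 1:2) {
    blk <- p2$blocks[[ax]]
    expect_equal(sum(blk$height) + 0.1 * (nrow(blk) - 1), 1, tolerance = 1e-9)
  }
  # ribbon widths: count/n, per-axis extent = width * usable length
  usable <- 1 - 0.1 * (nrow(p2$blocks[[1]]) - 1)
  expect_equal(p2$ribbons$h_a, p2$ribbons$count / p2$n * usable,
               tolerance = 1e-9)

  single <- make_model(rep(1, 10), rep(1:2, 5))
  single <- layout_parallel_sets(single, gap = 0)
  expect_equal(single$blocks[[1]]$height, 1)

  expect_error(layout_parallel_sets(p, gap = 0.6), "gap")
})

test_that("ribbon stubs tile each block contiguously", {
  set.seed(5)
  p <- make_model(canonical_labels(sample.int(3, 60, replace = TRUE)),
                  canonical_labels(sample.int(3, 60, replace = TRUE)),
                  gap = 0.05)
  for (ax in 1:2) {
    own <- c("label_a", "label_b")[ax]
    ycol <- c("y_a", "y_b")[ax]; hcol <- c("h_a", "h_b")[ax]
    for (l in p$blocks[[ax]]$label) {
      rb <- p$ribbons[p$ribbons[[own]] == l, ]
      rb <- rb[order(rb[[ycol]]), ]
      blk <- p$blocks[[ax]][p$blocks[[ax]]$label == l, ]
      expect_equal(rb[[ycol]][1], blk$y, tolerance = 1e-9)
      expect_equal(sum(rb[[hcol]]), blk$height, tolerance = 1e-9)
      if (nrow(rb) > 1)
        expect_equal(rb[[ycol]][-1],
                     (rb[[ycol]] + rb[[hcol]])[-nrow(rb)], tolerance = 1e-9)
    }
  }
})

test_that("subgroup selection resolves blocks and ribbons with set union", {
  p <- make_model(c(1, 1, 2, 2, 2), c(1, 2, 1, 2, 2))
  blk <- select_subgroup(p, "g1", blocks = list(c(1, 1)))
  expect_setequal(blk$member_ids, c("S1", "S2"))

  rib <- select_subgroup(p, "g2", ribbons = list(c(1, 1), c(2, 2)))
  expect_setequal(rib$member_ids, c("S1", "S4", "S5"))

  both <- select_subgroup(p, "g3", blocks = list(c(1, 1)),
                          ribbons = list(c(1, 2)))
  expect_setequal(both$member_ids, c("S1", "S2"))  # ribbon is a subset

  expect_error(select_subgroup(p, "bad", ribbons = list(c(9, 9))), "\\(9,9\\)")
  expect_error(select_subgroup(p, "none"), "no blocks or ribbons")
})

test_that("selection algebra: union of parts = union of selections", {
  set.seed(9)
  p <- make_model(canonical_labels(sample.int(3, 50, replace = TRUE)),
                  canonical_labels(sample.int(3, 50, replace = TRUE)))
  parts <- lapply(seq_len(nrow(p$ribbons)),
                  function(r) c(p$ribbons$label_a[r], p$ribbons$label_b[r]))
  r1 <- parts[1:2]; r2 <- parts[3:4]
  sep <- union(select_subgroup(p, "a", ribbons = r1)$member_ids,
               select_subgroup(p, "b", ribbons = r2)$member_ids)
  joint <- select_subgroup(p, "ab", ribbons = c(r1, r2))$member_ids
  expect_setequal(joint, sep)
})

test_that("complement_subgroup is an involution and rejects empty results", {
  p <- make_model(c(1, 1, 2, 2, 2), c(1, 2, 1, 2, 2))
  s <- select_subgroup(p, "s", blocks = list(c(1, 1)))
  comp <- complement_subgroup(p, s)
  expect_length(comp$member_ids, 3)
  back <- complement_subgroup(p, comp, "again")
  expect_setequal(back$member_ids, s$member_ids)

  full <- select_subgroup(p, "all", blocks = list(c(1, 1), c(1, 2)))
  expect_error(complement_subgroup(p, full), "empty")
})

test_that("parallel-sets JSON serialization carries the rendering contract", {
  p <- make_model(c(1, 1, 2, 2, 2), c(1, 2, 1, 2, 2), gap = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  write_parallel_sets_json(p, path, include_members = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$n, 5)
  expect_equal(obj$gap, 0.02)
  expect_equal(nrow(obj$ribbons), 4)
  expect_equal(obj$ribbons$count, p$ribbons$count)
  expect_equal(obj$axes$k, c(2, 2))
})
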