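test_that("the score is the weighted allele count", {
  panel <- snp_panel(c("s1", "s2"), c("A", "C"), c(0.3, 0.4), c(0.5, 0.3))
  g <- matrix(c(1L, 0L, 2L, 0L, 1L, 0L, 1L, 2L, 2L, 2L), nrow = 5,
              dimnames = list(NULL, c("s1", "s2")))
  prs <- compute_prs(g, panel)
  expect_equal(prs$prs_raw, c(1 * 0.5 + 0 * 0.3,   # 0.5
                              0 * 0.5 + 1 * 0.3,   # 0.3
                              2 * 0.5 + 2 * 0.3,   # 1.6
                              0 * 0.5 + 2 * 0.3,   # 0.6
                              1 * 0.5 + 2 * 0.3))  # 1.1
  expect_equal(prs$prs_raw[3], 1.6)
  expect_equal(prs$prs_std, as.numeric(scale(prs$prs_raw)))
})

test_that("a zero-genotype row scores zero", {
  panel <- snp_panel(paste0("s", 1:3), c("A", "C", "G"), rep(0.5, 3),
                     c(0.2, 0.4, 0.6))
  g <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L), c(2L, 0L, 1L), c(0L, 2L, 2L),
             c(1L, 2L, 0L), c(2L, 2L, 2L))
  colnames(g) <- panel$snp_id
  expect_equal(compute_prs(g, panel)$prs_raw[1], 0)
})

test_that("column order does not matter (ids are matched)", {
  panel <- snp_panel(paste0("s", 1:4), rep("A", 4), rep(0.5, 4),
                     c(0.1, 0.2, 0.3, 0.4))
  set.seed(1)
  g <- matrix(sample(0:2, 40, replace = TRUE), 10,
              dimnames = list(NULL, paste0("s", 1:4)))
  shuffled <- g[, c(3, 1, 4, 2)]
  expect_equal(compute_prs(g, panel)$prs_raw,
               compute_prs(shuffled, panel)$prs_raw)
})

test_that("missing panel SNPs and missing calls are errors", {
  panel <- snp_panel(paste0("s", 1:3), rep("A", 3), rep(0.5, 3), rep(0.1, 3))
  g <- matrix(0L, 5, 2, dimnames = list(NULL, c("s1", "s2")))
  expect_error(compute_prs(g, panel), "absent.*s3")
  g2 <- matrix(0L, 5, 3, dimnames = list(NULL, paste0("s", 1:3)))
  g2[2, 3] <- NA
  expect_error(compute_prs(g2, panel), "missing genotype")
  g3 <- matrix(3L, 5, 3, dimnames = list(NULL, paste0("s", 1:3)))
  expect_error(compute_prs(g3, panel), "0/1/2")
  expect_error(compute_prs(matrix(0L, 2, 2), panel), "column names")
})

test_that("the score is linear in the weights", {
  panel <- snp_panel(paste0("s", 1:5), rep("A", 5), rep(0.4, 5),
                     c(0.1, 0.2, 0.3, 0.4, 0.5))
  set.seed(2)
  g <- matrix(sample(0:2, 100, replace = TRUE), 20,
              dimnames = list(NULL, paste0("s", 1:5)))
  doubled <- snp_panel(panel$snp_id, panel$risk_allele, panel$allele_freq,
                       2 * panel$weight)
  a <- compute_prs(g, panel)
  b <- compute_prs(g, doubled)
  expect_equal(b$prs_raw, 2 * a$prs_raw)
  # standardized scores and groups are scale-invariant
  expect_equal(b$prs_std, a$prs_std)
  expect_identical(b$genetic_group, a$genetic_group)
})

test_that("quintile groups split 1..100 as 20/60/20", {
  grp <- assign_genetic_groups(1:100)
  expect_identical(as.integer(table(grp)), c(20L, 60L, 20L))
  expect_identical(levels(grp), c("low", "intermediate", "high"))
  expect_false(is.ordered(grp))
  # boundary scores stay intermediate on both sides
  q <- quantile(1:100, c(0.2, 0.8), names = FALSE)
  expect_true(all(grp[1:100 < q[1]] == "low"))
  expect_true(all(grp[1:100 > q[2]] == "high"))
})

test_that("tied scores resolve deterministically to intermediate", {
  x <- c(rep(1, 30), rep(2, 15), rep(3, 10), rep(4, 15), rep(5, 30))
  grp <- assign_genetic_groups(x)
  # the 20th percentile equals the smallest value and the 80th the largest,
  # so nothing is strictly outside them
  expect_true(all(grp == "intermediate"))
})

test_that("groups are invariant to strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(500)
  expect_identical(assign_genetic_groups(x),
                   assign_genetic_groups(exp(x)))
  expect_identical(assign_genetic_groups(x),
                   assign_genetic_groups(100 + 3 * x))
})

test_that("degenerate score vectors are rejected", {
  expect_error(assign_genetic_groups(rep(1, 50)), "fewer than 5 distinct")
  expect_error(assign_genetic_groups(c(1, 2, NA, 4, 5, 6)), "finite")
})

test_that("the score result round-trips to disk", {
  panel <- snp_panel(paste0("s", 1:3), rep("A", 3), rep(0.5, 3), rep(0.3, 3))
  set.seed(4)
  g <- matrix(sample(0:2, 60, replace = TRUE), 20,
              dimnames = list(sprintf("P%03d", 1:20), paste0("s", 1:3)))
  prs <- compute_prs(g, panel)
  path <- tempfile(fileext = ".csv")
  write_prs_result(prs, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$prs_raw, prs$prs_raw, tolerance = 1e-10)
  expect_identical(back$participant_id, prs$participant_id)
})
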