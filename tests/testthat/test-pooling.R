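# Static and run-wise reference pools.

test_that("normals are filtered by depth cutoff and sorted ascending with stable ties", {
  tmpl <- make_template(c(100, 80))
  covs <- list(make_cov(tmpl, 90, "A"), make_cov(tmpl, 150, "B"),
               make_cov(tmpl, 120, "C"))
  sel <- select_normals(covs, 100)
  expect_equal(vapply(sel, function(s) s$sample_id, ""), c("C", "B"))

  expect_error(select_normals(covs, 1000), "no eligible")

  ties <- list(make_cov(tmpl, 150, "Zed"), make_cov(tmpl, 150, "Abe"))
  sel <- select_normals(ties, 100)
  expect_equal(vapply(sel, function(s) s$sample_id, ""), c("Abe", "Zed"))
})

test_that("pool construction yields M = N - K + 1 sliding groups sharing K - 1 members", {
  tmpl <- make_template(c(100, 80))
  mk <- function(n) lapply(seq_len(n), function(i)
    make_cov(tmpl, 100 + i, sprintf("S%02d", i)))

  expect_length(build_static_pools(mk(10), 8, tmpl)$pools, 3L)   # M = 10 - 8 + 1
  expect_length(build_static_pools(mk(8), 8, tmpl)$pools, 1L)    # N = K

  ps <- build_static_pools(mk(5), 2, tmpl)
  expect_length(ps$pools, 4L)
  for (j in 1:3) {
    shared <- intersect(ps$pools[[j]]$members, ps$pools[[j + 1]]$members)
    expect_length(shared, 1L)                                    # K - 1 = 1
  }
  expect_error(build_static_pools(mk(5), 8, tmpl), "N = 5 < K = 8")
  expect_error(build_static_pools(mk(5), 1, tmpl), "at least 2")

  # enumeration oracle over randomised N, K
  set.seed(13)
  for (i in 1:20) {
    N <- sample(3:15, 1)
    K <- sample(2:N, 1)
    normals <- mk(N)
    ps <- build_static_pools(normals, K, tmpl)
    ids <- sprintf("S%02d", seq_len(N))
    orc <- oracle_pools(ids, K)
    expect_length(ps$pools, length(orc))
    for (j in seq_along(orc)) expect_equal(ps$pools[[j]]$members, orc[[j]])
    # pool means non-decreasing in pool_id
    pm <- vapply(ps$pools, function(p) p$pool_mean_depth, 0)
    expect_true(all(diff(pm) >= 0))
  }
})

test_that("mean_TRSW is the unweighted mean of member window means", {
  tmpl <- make_template(c(134, 60))
  set.seed(21)
  covs <- lapply(1:4, function(i)
    make_cov(tmpl, rpois(tmpl$n_positions, 100 + 10 * i), sprintf("S%d", i)))
  covs <- select_normals(covs, 0)
  ps <- build_static_pools(covs, 4, tmpl)
  wm <- sapply(covs, window_means, template = tmpl)
  expect_equal(ps$pools[[1]]$mean_trsw, rowMeans(wm), tolerance = 1e-12)

  # identical members: pool reference equals any member's window means
  same <- lapply(1:3, function(i) make_cov(tmpl, 150, sprintf("T%d", i)))
  ps2 <- build_static_pools(same, 3, tmpl)
  expect_equal(ps2$pools[[1]]$mean_trsw, window_means(same[[1]], tmpl))
})

test_that("pool selection minimises depth distance, breaking ties low", {
  tmpl <- make_template(100)
  mk_ps <- function(means) {
    covs <- lapply(seq_along(means), function(i)
      make_cov(tmpl, means[i], sprintf("P%d", i)))
    structure(list(
      pools = lapply(seq_along(covs), function(i)
        make_pool(covs[i], tmpl, pool_id = i)),
      K = 2L, N = length(covs), lot_id = "lot01"), class = "pool_set")
  }
  ps <- mk_ps(c(150, 190, 260))
  q <- make_cov(tmpl, 200, "Q")
  expect_equal(select_pool(q, ps)$pool_mean_depth, 190)

  # exactly midway -> lower-depth pool
  ps2 <- mk_ps(c(180, 220))
  expect_equal(select_pool(q, ps2)$pool_mean_depth, 180)

  # argmin oracle over random pools, and invariance to pool order
  set.seed(31)
  for (i in 1:10) {
    means <- sample(100:400, 50)
    ps3 <- mk_ps(means)
    got <- select_pool(q, ps3)$pool_mean_depth
    expect_equal(abs(got - 200), min(abs(means - 200)))
    perm <- ps3
    perm$pools <- perm$pools[sample(50)]
    expect_equal(select_pool(q, perm)$pool_mean_depth, got)
  }
})

test_that("cross-lot pool selection is refused unless overridden", {
  tmpl <- make_template(100)
  covs <- lapply(1:3, function(i) make_cov(tmpl, 100 + i, sprintf("S%d", i)))
  ps <- build_static_pools(covs, 3, tmpl, lot_id = "lot01")
  q <- make_cov(tmpl, 102, "Q", lot_id = "lot02")
  expect_error(select_pool(q, ps), "batch effects")
  expect_s3_class(select_pool(q, ps, allow_cross_lot = TRUE), "static_pool")
})

test_that("run-wise pools exclude the query and reuse the static-pool maths", {
  tmpl <- make_template(c(100, 80))
  set.seed(41)
  run <- lapply(1:8, function(i)
    make_cov(tmpl, rpois(tmpl$n_positions, 150), sprintf("R%d", i)))
  pool <- build_runwise_pool(run, "R3", tmpl)
  expect_length(pool$members, 7L)
  expect_false("R3" %in% pool$members)
  expect_true(pool$runwise)

  # same member set through build_static_pools gives the same mean_TRSW
  members <- run[vapply(run, function(s) s$sample_id, "") != "R3"]
  members <- select_normals(members, 0)
  ps <- build_static_pools(members, 7, tmpl)
  expect_equal(pool$mean_trsw, ps$pools[[1]]$mean_trsw, tolerance = 1e-12)

  expect_error(build_runwise_pool(run[1:2], "R1", tmpl), "insufficient run samples")
})

test_that("pool stores round-trip through the on-disk format", {
  tmpl <- make_template(c(134, 60))
  set.seed(51)
  covs <- lapply(1:6, function(i)
    make_cov(tmpl, rpois(tmpl$n_positions, 140 + i), sprintf("S%d", i)))
  covs <- select_normals(covs, 0)
  ps <- build_static_pools(covs, 4, tmpl, lot_id = "lotX")
  dir <- tempfile()
  write_pool_set(ps, tmpl, dir)
  back <- read_pool_set(dir, tmpl)
  expect_equal(length(back$pools), length(ps$pools))
  expect_equal(back$K, ps$K)
  expect_equal(back$lot_id, "lotX")
  for (j in seq_along(ps$pools)) {
    expect_equal(back$pools[[j]]$members, ps$pools[[j]]$members)
    expect_equal(back$pools[[j]]$mean_trsw, ps$pools[[j]]$mean_trsw,
                 tolerance = 1e-6)
    expect_equal(back$pools[[j]]$pool_mean_depth, ps$pools[[j]]$pool_mean_depth,
                 tolerance = 1e-6)
  }
  # mismatched template is refused
  tmpl2 <- make_template(c(134, 61))
  expect_error(read_pool_set(dir, tmpl2), "does not match")
})
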