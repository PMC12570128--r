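make_trace <- function(time, force, ...) force_trace(time, force, source = "toysim", ...)

test_that("max rupture force finds the global peak with earliest-tie rule", {
  tri <- make_trace(0:10, c(0:5 * 10, 4:0 * 10))
  mx <- max_rupture_force(tri)
  expect_equal(mx$f_max, 50)
  expect_equal(mx$t_at_max, 5)
  flat <- make_trace(0:4, rep(10, 5))
  expect_equal(max_rupture_force(flat)$t_at_max, 0)
  set.seed(31)
  noisy <- make_trace(seq_len(1e4), rnorm(1e4, 50, 20))
  mx2 <- max_rupture_force(noisy)
  i <- which.max(noisy$force)  # brute-force scan
  expect_identical(mx2$f_max, noisy$force[i])
  expect_identical(mx2$t_at_max, noisy$time[i])
  expect_true(all(mx2$f_max >= noisy$force))
})

test_that("smoothed maxima use the running mean only when asked", {
  set.seed(32)
  f <- rnorm(201, 10, 1); f[100] <- 50  # single-sample spike
  tr <- make_trace(seq_along(f), f)
  raw <- max_rupture_force(tr)
  sm <- max_rupture_force(tr, smooth_window = 51)
  expect_equal(raw$f_max, 50)
  expect_lt(sm$f_max, 15)
  expect_equal(running_mean(f, 0), f)
  expect_equal(running_mean(rep(3, 10), 5), rep(3, 10))
})

test_that("force vs distance pairs by time and tolerates non-monotone distance", {
  tr <- make_trace(0:4, c(0, 10, 30, 20, 5))
  d <- c(10, 11, 10.5, 12, 13)  # physical recoil
  fd <- force_vs_distance(tr, d)
  expect_equal(fd$distance, d)
  expect_equal(fd$force[fd$distance == 10.5], 30)
  expect_error(force_vs_distance(tr, 1:3), class = "pullfan_input_error")
})

test_that("replica aggregation: mean and SD with the n-1 convention", {
  t1 <- make_trace(0:10, rep(1, 11))
  t3 <- make_trace(0:10, rep(3, 11))
  ens <- aggregate_replicas(list(t1, t3), grid_dt = 1)
  expect_equal(unique(ens$mean_force), 2)
  expect_equal(unique(ens$sd_force), sqrt(2), tolerance = 1e-12)
  # identical replicas: SD identically zero, mean equals the trace
  ens2 <- aggregate_replicas(list(t1, t1, t1))
  expect_true(all(ens2$sd_force == 0))
  expect_equal(unique(ens2$mean_force), 1)
  # single replica: SD defined as zero
  ens1 <- aggregate_replicas(list(t1))
  expect_true(all(ens1$sd_force == 0))
})

test_that("aggregation grid spans only the overlapping time range", {
  a <- make_trace(seq(0, 10, 0.5), sin(seq(0, 10, 0.5)))
  b <- make_trace(seq(2, 14, 0.25), cos(seq(2, 14, 0.25)))
  ens <- aggregate_replicas(list(a, b))
  expect_gte(min(ens$common_time), 2)
  expect_lte(max(ens$common_time), 10)
  expect_equal(diff(ens$common_time)[1], 0.25)  # smallest native interval
  c_ <- make_trace(20:25, rep(1, 6))
  expect_error(aggregate_replicas(list(a, c_)), "overlap", class = "pullfan_input_error")
})

test_that("replica mean/SD match direct computation on synthetic ensembles", {
  set.seed(33)
  grid <- seq(0, 20, 0.5)
  traces <- lapply(1:5, function(r)
    make_trace(grid, 50 * sin(grid / 3) + rnorm(length(grid), 0, 2), replica_id = r))
  ens <- aggregate_replicas(traces, grid_dt = 0.5)
  M <- sapply(traces, function(tr) approx(tr$time, tr$force, xout = ens$common_time)$y)
  expect_equal(ens$mean_force, rowMeans(M), tolerance = 1e-12)
  expect_equal(ens$sd_force, apply(M, 1, sd), tolerance = 1e-12)
})

test_that("hydrogen-bond criterion: distance and angle gates", {
  # linear N-H...O at 2.8 A and 180 deg passes the 3.5 A / 150 deg default
  frame <- rbind(c(0, 0, 0),      # N (donor)
                 c(0, 0, 1),      # H
                 c(0, 0, 2.8))    # O (acceptor)
  donors <- data.frame(d = 1, h = 2, frag = 1)
  expect_equal(count_hbonds(frame, donors, 3L), 1L)
  # distance failure
  frame2 <- frame; frame2[3, 3] <- 5
  expect_equal(count_hbonds(frame2, donors, 3L), 0L)
  # angle failure: acceptor perpendicular at H
  frame3 <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 2.5, 1))
  expect_equal(count_hbonds(frame3, donors, 3L), 0L)
  # intra-fragment pairs are never counted
  acc_same <- data.frame(a = 3, frag = 1)
  expect_equal(count_hbonds(frame, donors, acc_same), 0L)
  expect_error(hbond_criterion(d_max = -1), class = "pullfan_config_error")
  expect_error(count_hbonds(frame, donors, 99L), class = "pullfan_input_error")
})

test_that("hbond counts equal the brute-force double loop on random frames", {
  set.seed(34)
  crit <- hbond_criterion()
  for (rep in 1:100) {
    n <- 20
    frame <- matrix(runif(3 * n, 0, 8), ncol = 3)
    donors <- data.frame(d = sample(1:5, 4), h = sample(6:10, 4), frag = 1)
    acceptors <- data.frame(a = sample(11:20, 5), frag = 2)
    got <- count_hbonds(frame, donors, acceptors, crit)
    want <- 0L
    for (i in 1:4) for (j in 1:5) {
      D <- frame[donors$d[i], ]; H <- frame[donors$h[i], ]; A <- frame[acceptors$a[j], ]
      dda <- sqrt(sum((D - A)^2))
      ang <- acos(sum((D - H) * (A - H)) /
                    sqrt(sum((D - H)^2) * sum((A - H)^2))) * 180 / pi
    if (dda <= crit$d_max && ang >= crit$angle_min) want <- want + 1L
    }
    expect_identical(got, want)
  }
})

test_that("hbond count is invariant under rigid rotation and translation", {
  set.seed(35)
  frame <- matrix(runif(30, 0, 6), ncol = 3)
  donors <- data.frame(d = 1:3, h = 4:6, frag = 1)
  acceptors <- data.frame(a = 7:10, frag = 2)
  base <- count_hbonds(frame, donors, acceptors)
  for (i in 1:5) {
    R <- random_rotation()
    t <- runif(3, -100, 100)
    moved <- frame %*% t(R) + matrix(t, nrow(frame), 3, byrow = TRUE)
    expect_identical(count_hbonds(moved, donors, acceptors), base)
  }
})

test_that("hbond series tracks a scripted bond break at an exact frame", {
  donors <- data.frame(d = 1, h = 2, frag = 1)
  acceptors <- data.frame(a = 3, frag = 2)
  frames <- lapply(1:10, function(k) {
    gap <- if (k < 6) 2.8 else 6.0  # bond scripted to break at frame 6
    rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, gap))
  })
  traj <- structure(list(frames = frames, structure = NULL), class = "trajectory")
  counts <- hbond_series(traj, donors, acceptors)
  expect_equal(counts, c(rep(1L, 5), rep(0L, 5)))
  # static trajectory gives a constant series
  traj2 <- structure(list(frames = frames[rep(1, 4)], structure = NULL),
                     class = "trajectory")
  expect_equal(hbond_series(traj2, donors, acceptors), rep(1L, 4))
})

test_that("anisotropy table has one ordered row per direction with honest SDs", {
  set.seed(36)
  summaries <- lapply(1:9, function(i) {
    traces <- lapply(1:5, function(r)
      make_trace(0:50, rnorm(51, 20 * i, 2), replica_id = r))
    rupture_summary(traces, sprintf("dir_%d", i), theta = i, phi = 0)
  })
  tab <- anisotropy_table(summaries)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$label, sprintf("dir_%d", 1:9))
  expect_equal(tab$n_replicas, rep(5L, 9))
  # values equal direct recomputation from the traces
  s1 <- summaries[[1]]
  expect_equal(tab$mean_f_max[1], mean(s1$replicas$f_max))
  expect_equal(tab$sd_f_max[1], sd(s1$replicas$f_max))
  # single replica: SD column is zero
  one <- rupture_summary(list(make_trace(0:10, 0:10)), "solo")
  expect_equal(anisotropy_table(list(one))$sd_f_max, 0)
  expect_error(anisotropy_table(list(one, one)), "duplicate",
               class = "pullfan_input_error")
})

test_that("analysis outputs are deterministic given identical inputs", {
  set.seed(37)
  traces <- lapply(1:3, function(r) make_trace(0:100, rnorm(101, 50, 5)))
  a <- aggregate_replicas(traces)
  b <- aggregate_replicas(traces)
  expect_identical(a, b)
})
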