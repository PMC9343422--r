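sync_row <- function(subject, condition, trial, direction, n, m, V, ac,
                     plv = abs(V)) {
  data.frame(subject = subject, condition = condition, trial = trial,
             direction = direction, sensor_n = n, sensor_m = m,
             plv = plv, theta = 0, V = V, ac = ac, degenerate = FALSE)
}

test_that("average_over_trials is the arithmetic mean across trials", {
  one <- sync_row("s1", "EO", 1L, "ML", 1, 2, V = 0.6, ac = 0.4)
  expect_equal(average_over_trials(one)$V, 0.6)
  expect_equal(average_over_trials(one)$ac, 0.4)

  two <- rbind(one, sync_row("s1", "EO", 2L, "ML", 1, 2, V = 0.8, ac = 0.6))
  avg <- average_over_trials(two)
  expect_equal(avg$V, 0.7)
  expect_equal(avg$ac, 0.5)
  expect_equal(avg$n_trials, 2L)
  expect_equal(average_over_trials(two, rule = "first")$V, 0.6)

  # 5 random trials match the direct summation oracle to 1e-12
  set.seed(2)
  vs <- runif(5, -1, 1); acs <- runif(5, -1, 1)
  five <- do.call(rbind, lapply(1:5, function(i)
    sync_row("s2", "EC", i, "AP", 3, 4, V = vs[i], ac = acs[i])))
  avg <- average_over_trials(five)
  expect_equal(avg$V, sum(vs) / 5, tolerance = 1e-12)
  expect_equal(avg$ac, sum(acs) / 5, tolerance = 1e-12)
  expect_error(average_over_trials(one[0, ]), "no trials")
})

test_that("group_mean_sd uses the n-1 formula and is permutation invariant", {
  subj <- data.frame(subject = paste0("s", 1:4), condition = "EO",
                     direction = "ML", sensor_n = 1L, sensor_m = 2L,
                     V = c(0.2, 0.4, 0.6, 0.8), ac = c(0.2, 0.4, 0.6, 0.8))
  g <- group_mean_sd(subj, metric = "V")
  expect_equal(g$mean, 0.5, tolerance = 1e-12)
  hand_sd <- sqrt(sum((c(0.2, 0.4, 0.6, 0.8) - 0.5)^2) / 3)
  expect_equal(g$sd, hand_sd, tolerance = 1e-12)
  expect_equal(g$n_subjects, 4L)
  expect_equal(as.character(g$category), "M")

  shuffled <- subj[c(3, 1, 4, 2), ]
  expect_equal(group_mean_sd(shuffled, metric = "V")$mean, g$mean)
  expect_equal(group_mean_sd(shuffled, metric = "V")$sd, g$sd)

  ident <- transform(subj, V = 0.5)
  g2 <- group_mean_sd(ident, metric = "V")
  expect_equal(g2$mean, 0.5)
  expect_equal(g2$sd, 0)

  expect_error(group_mean_sd(subj[1, ], metric = "V"), "at least 2 subjects")
})

test_that("categorize matches the printed category bands", {
  # boundary cells pinned by the published tables
  expect_equal(as.character(categorize(c(0.84, 0.80, 0.60, 0.40, 0.39))),
               c("VS", "VS", "S", "M", "W"))
  # negative values are weak; total monotone step function
  expect_equal(as.character(categorize(c(-1, -0.2, 0, 0.5999, 0.7999, 1))),
               c("W", "W", "W", "M", "S", "VS"))
  v <- seq(-1, 1, by = 0.01)
  lv <- as.integer(factor(as.character(categorize(v)),
                          levels = c("W", "M", "S", "VS")))
  expect_true(all(diff(lv) >= 0))
  expect_error(categorize(1.2), "\\[-1, 1\\]")
})

test_that("every bundled reference cell agrees with the banding rule", {
  ref <- reference_group_stats()
  expect_equal(nrow(ref), 2 * 2 * 2 * 21)
  expect_equal(as.character(categorize(ref$mean)), ref$category)
})

test_that("find_clusters recovers runs and link sites (published ML/EO column)", {
  ref <- reference_group_stats()
  col <- ref[ref$metric == "AAC" & ref$direction == "ML" &
               ref$condition == "EO", ]
  col <- col[order(col$sensor_n), "mean"]
  # with high = 0.8: the single very-strong run 9-12
  seg <- find_clusters(col, high = 0.8)
  expect_equal(seg$coherent_runs, data.frame(from = 9L, to = 12L))
  # with the standard 0.6 threshold: runs 1-2, 5-6 and 7-17
  seg6 <- find_clusters(col, high = 0.6, low = 0.4)
  expect_equal(seg6$coherent_runs,
               data.frame(from = c(1L, 5L, 7L), to = c(2L, 6L, 17L)))
  # link sites are the pairs below 0.4
  expect_equal(seg6$link_sites$n, c(2L, 3L, 6L, 18L, 19L))
})

test_that("find_clusters equals the exhaustive-window oracle on random input", {
  set.seed(9)
  for (rep in 1:20) {
    vals <- runif(21, -0.2, 1)
    seg <- find_clusters(vals)
    expect_equal(seg$coherent_runs, oracle_find_runs(vals, 0.6))
    expect_equal(seg$link_sites$n, which(vals < 0.4))
  }
  # trivial cases
  seg <- find_clusters(rep(0.9, 21))
  expect_equal(seg$coherent_runs, data.frame(from = 1L, to = 22L))
  expect_equal(nrow(seg$link_sites), 0)
  # invariance to values moving strictly inside (low, high)
  vals <- c(0.9, 0.9, 0.5, 0.2, 0.7)
  s1 <- find_clusters(vals)
  vals[3] <- 0.45
  s2 <- find_clusters(vals)
  expect_equal(s1$coherent_runs, s2$coherent_runs)
  expect_equal(s1$link_sites, s2$link_sites)
  expect_error(find_clusters(runif(20), n_sensors = 22), "expected 21")
})

test_that("region_label maps adjacent pairs to anatomical regions", {
  expect_equal(region_label(1, 2), "head and upper neck")
  expect_equal(region_label(10, 11), "middle thorax")
  expect_equal(region_label(19, 20), "lower lumbar")
  expect_equal(region_label(21, 22), "lower lumbar and pelvis")
  # full coverage, cranial to caudal
  all21 <- region_label(1:21, 2:22)
  expect_equal(unique(all21),
               c("head and upper neck", "upper neck", "lower neck",
                 "upper thorax", "middle thorax", "lower thorax",
                 "upper lumbar", "lower lumbar", "lower lumbar and pelvis"))
  expect_error(region_label(1, 3), "adjacent")
})

test_that("render_heatmaps writes deterministic files and masks missing cells", {
  ref <- reference_group_stats()
  grp <- ref[ref$metric == "AAC", ]
  out1 <- file.path(tempdir(), "hm1"); out2 <- file.path(tempdir(), "hm2")
  expect_warning(
    render_heatmaps(grp[grp$condition == "EO" & grp$direction == "ML", ],
                    file.path(tempdir(), "hm0")),
    "masked")
  p1 <- suppressWarnings(render_heatmaps(grp, out1))
  expect_equal(length(p1), 8)  # mean + sd for 2 conditions x 2 directions
  expect_true(all(file.exists(p1)))
  expect_true(all(file.size(p1) > 0))
  suppressWarnings(p2 <- render_heatmaps(grp, out2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
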