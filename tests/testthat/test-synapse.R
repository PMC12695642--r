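# synapse census, matching, hotspots, score cleaning, confusion metrics

nodes_df <- function(z, y = 0, x = 0, pass = 1, dendrite = NULL) {
  df <- data.frame(z_nm = z, y_nm = rep(y, length.out = length(z)),
                   x_nm = rep(x, length.out = length(z)),
                   pass_index = rep(pass, length.out = length(z)))
  if (!is.null(dendrite)) df$dendrite_id <- dendrite
  df
}

test_that("census merges chains single-link and respects the radius", {
  expect_equal(nrow(build_census(nodes_df(numeric(0)))$entries), 0)

  # chain 0, 250, 500 nm with radius 300: one entry
  chain <- build_census(nodes_df(c(0, 250, 500)), 300)
  expect_equal(nrow(chain$entries), 1)
  expect_equal(chain$entries$n_members, 3)
  expect_equal(chain$entries$z_nm, 250)

  # boundary: exactly 300 merges, 301 does not
  expect_equal(nrow(build_census(nodes_df(c(0, 300)), 300)$entries), 1)
  expect_equal(nrow(build_census(nodes_df(c(0, 301)), 300)$entries), 2)

  # first_pass_detected = min pass among members
  cen <- build_census(nodes_df(c(0, 100), pass = c(3, 2)), 300)
  expect_equal(cen$entries$first_pass_detected, 2L)
  expect_error(build_census(nodes_df(0), 0), "merge_radius")
})

test_that("census equals the brute-force clustering oracle and is
           permutation invariant", {
  set.seed(21)
  for (rep in 1:5) {
    pos <- matrix(runif(3 * 60, 0, 3000), ncol = 3)
    df <- data.frame(z_nm = pos[, 1], y_nm = pos[, 2], x_nm = pos[, 3],
                     pass_index = sample(1:3, 60, TRUE))
    cen <- build_census(df, 300)
    oracle <- oracle_single_link(pos, 300)
    expect_equal(nrow(cen$entries), length(unique(oracle)))
    # identical membership partition (compare sorted member lists)
    got <- lapply(cen$members, sort)
    want <- unname(split(seq_len(60), oracle))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    # permutation invariance of the partition
    perm <- sample(60)
    cen_p <- build_census(df[perm, ], 300)
    expect_equal(nrow(cen_p$entries), nrow(cen$entries))
    expect_setequal(round(cen_p$entries$z_nm, 9), round(cen$entries$z_nm, 9))
  }
})

test_that("match_detections flags entries within radius, monotone in radius", {
  set.seed(3)
  pos <- matrix(seq(0, 49) * 1000, ncol = 1)
  cen <- build_census(nodes_df(pos[, 1]), 300)
  expect_equal(nrow(cen$entries), 50)

  # 60% of entries get a query node at 100-290 nm
  hit <- seq_len(30)
  q <- nodes_df(cen$entries$z_nm[hit] + runif(30, 100, 290))
  m <- match_detections(cen, q, 300)
  expect_equal(mean(m$detected), 0.6)
  expect_equal(nrow(m$unmatched), 0)

  m0 <- match_detections(cen, nodes_df(numeric(0)), 300)
  expect_false(any(m0$detected))

  mc <- match_detections(cen, nodes_df(cen$entries$z_nm), 300)
  expect_true(all(mc$detected))
  expect_equal(nrow(mc$unmatched), 0)

  # monotone non-decreasing detected count in radius
  qq <- nodes_df(cen$entries$z_nm + runif(50, 0, 600))
  counts <- vapply(c(100, 300, 500, 700),
                   function(r) sum(match_detections(cen, qq, r)$detected),
                   numeric(1))
  expect_false(is.unsorted(counts))
})

test_that("hotspots are clusters of >= min_tags unmatched nodes", {
  iso <- nodes_df(c(0, 1000, 2000))
  expect_equal(nrow(find_hotspots(iso, 300)), 0)
  pair <- nodes_df(c(0, 200))
  hs <- find_hotspots(pair, 300)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$n_tags, 2L)
  set.seed(9)
  pos <- matrix(runif(120, 0, 2500), ncol = 3)
  df <- data.frame(z_nm = pos[, 1], y_nm = pos[, 2], x_nm = pos[, 3])
  hs2 <- find_hotspots(df, 300, min_tags = 2)
  oracle <- oracle_single_link(pos, 300)
  expect_equal(nrow(hs2), sum(table(oracle) >= 2))
  expect_error(find_hotspots(df, 300, min_tags = 1), "min_tags")
})

test_that("clean_scores drops bad annotators and incomplete regions", {
  set.seed(5)
  base <- sample(1:4, 250, TRUE)
  scores <- array(0L, c(250, 3, 2))
  for (a in 1:3) for (m in 1:2) scores[, a, m] <- base
  out <- clean_scores(scores, 0.4)
  expect_equal(out$kept_annotators, 1:3)
  expect_equal(length(out$kept_regions), 250)

  # anti-correlated annotator is dropped at min_xcorr = 0.4
  bad <- scores
  bad[, 3, 1] <- 5L - base
  out2 <- clean_scores(bad, 0.4)
  expect_equal(out2$dropped_annotators, 3L)

  # 10 rows with a 0: 240 retained (the 250 -> 240 cleanup)
  holes <- scores
  holes[sample(250, 10), 2, 2] <- 0L
  out3 <- clean_scores(holes, 0.4)
  expect_equal(length(out3$kept_regions), 240)

  expect_error(clean_scores(array(1L, c(10, 1, 2))), "remain")
  expect_error(clean_scores(array(7L, c(10, 3, 2))), "0..4")
})

test_that("confusion metrics match the printed formulas", {
  s <- confusion_summary(TP = 13, FP = 3, FN = 7)
  expect_equal(s$precision, 0.8125)
  expect_equal(s$recall, 0.65)
  expect_equal(s$f1, 0.7222, tolerance = 1e-4)
  expect_equal(s$f_beta, 0.6771, tolerance = 1e-4)
  # brute-force cross-check of F_beta from the definition
  expect_equal(s$f_beta, (1 + 4) * s$precision * s$recall /
                 (4 * s$precision + s$recall), tolerance = 1e-12)

  # beta = 1 equals F1; beta = 2 favors recall
  s1 <- confusion_summary(13, 3, 7, beta = 1)
  expect_equal(s1$f_beta, s1$f1)
  hiP <- confusion_summary(10, 1, 10, beta = 2)   # P > R: F2 < F1
  expect_lt(hiP$f_beta, hiP$f1)
  hiR <- confusion_summary(10, 10, 1, beta = 2)   # P < R: F2 > F1
  expect_gt(hiR$f_beta, hiR$f1)

  u <- confusion_summary(0, 0, 5)
  expect_true(is.na(u$precision))
  expect_false(u$precision_defined)
})

test_that("captcha confusion: identity, degenerate and counting checks", {
  set.seed(6)
  base <- sample(1:4, 60, TRUE)
  scores <- array(0L, c(60, 3, 2))
  for (a in 1:3) for (m in 1:2) scores[, a, m] <- base
  res <- captcha_confusion(scores)
  expect_equal(res$summary$precision, 1)
  expect_equal(res$summary$recall, 1)
  expect_equal(res$summary$f1, 1)

  # metrics from the 2x2 equal brute-force counting over regions
  set.seed(7)
  sc2 <- array(sample(1:4, 60 * 3 * 2, TRUE), c(60, 3, 2))
  r2 <- captcha_confusion(sc2)
  em <- apply(sc2[, , 1], 1, mean) >= 2.5
  px <- apply(sc2[, , 2], 1, mean) >= 2.5
  expect_equal(r2$summary$TP, sum(em & px))
  expect_equal(r2$summary$FN, sum(em & !px))
  expect_equal(sum(r2$table_4x4), 60 * 3)

  # all-PXCT-1 on mixed EM: recall 0, precision undefined and flagged
  sc3 <- sc2
  sc3[, , 2] <- 1L
  r3 <- captcha_confusion(sc3)
  expect_equal(r3$summary$recall, 0)
  expect_true(is.na(r3$summary$precision))
  expect_error(captcha_confusion(array(integer(0), c(0, 3, 2))), "empty")
  expect_error(captcha_confusion(sc2, cut = 5), "cut")
})

test_that("dendrite report reproduces per-pass fractions", {
  # single-pass fixture: 100% first pass
  em <- nodes_df(seq(0, 9) * 1000, pass = 1)
  rep1 <- dendrite_report(em, em)
  expect_equal(unname(rep1$em_pass_pct["1"]), 100)
  expect_equal(rep1$detected_fraction, 1)

  # generator with known per-pass probabilities recovers them
  set.seed(8)
  n <- 400
  centers <- seq_len(n) * 1000
  p_first <- 0.8
  pass <- ifelse(runif(n) < p_first, 1L, 3L)
  em2 <- nodes_df(centers, pass = pass)
  px_detect <- runif(n) < 0.65
  px2 <- nodes_df(centers[px_detect] + runif(sum(px_detect), -200, 200),
                  pass = sample(1:2, sum(px_detect), TRUE))
  rep2 <- dendrite_report(em2, px2)
  expect_equal(rep2$n_census, n)
  expect_lt(abs(mean(rep2$census$entries$first_pass_detected == 1) -
                  p_first), 3 * sqrt(p_first * (1 - p_first) / n))
  expect_lt(abs(rep2$detected_fraction - 0.65), 3 * sqrt(0.65 * 0.35 / n))
})
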