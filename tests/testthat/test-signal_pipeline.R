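test_that("SI is the log10 of the replicate mean plus pseudocount", {
  libs <- full_libs(1L)
  d <- enumerate_crosses(libs[[1]], libs[[2]])
  cid <- d$cross_id[d$background == "A"]
  colonies <- data.frame(cross_id = cid, replicate = 1:3,
                         normalized_size = c(100, 100, 100))
  si <- compute_si(colonies, d, pseudocount = 0)
  expect_equal(si$SI, 2)
  colonies$normalized_size <- 0
  expect_equal(compute_si(colonies, d, pseudocount = 1)$SI, 0)
})

test_that("SI matches an independent arithmetic oracle on random replicates", {
  tr <- screen_truth(n_edges = 10, seed = 4)
  scr <- simulate_screen(tr)
  si <- compute_si(scr$colonies, scr$design, pseudocount = 1)
  for (k in withr::with_seed(1, sample(nrow(si), 20))) {
    v <- scr$colonies$normalized_size[scr$colonies$cross_id == si$cross_id[k]]
    expect_equal(si$SI[k], log10(sum(v) / length(v) + 1))
    expect_equal(si$n_reps[k], length(v))
  }
})

test_that("colonies with no design entry are reported as orphans", {
  libs <- full_libs(1L)
  d <- enumerate_crosses(libs[[1]], libs[[2]])
  colonies <- data.frame(cross_id = "ghost", replicate = 1,
                         normalized_size = 1)
  expect_error(compute_si(colonies, d), "ghost")
})

test_that("replicate correlations hit the exact and analytic expectations", {
  libs <- full_libs(4L)
  d <- enumerate_crosses(libs[[1]], libs[[2]])
  dA <- d[d$background == "A", ]
  v <- withr::with_seed(2, runif(nrow(dA), 0, 100))
  colonies <- data.frame(cross_id = rep(dA$cross_id, each = 2),
                         replicate = rep(1:2, nrow(dA)),
                         normalized_size = rep(v, each = 2))
  rr <- replicate_reproducibility(colonies, d)
  expect_equal(rr$r, 1)                      # identical replicates

  # replicate 2 = reflected replicate 1 (on the log scale) -> r = -1
  lv <- log10(v + 1)
  colonies$normalized_size[colonies$replicate == 2] <-
    10^(mean(lv) - (lv - mean(lv))) - 1
  expect_equal(replicate_reproducibility(colonies, d)$r, -1)

  # noise sigma = 0.05 on a 24x24 single-species screen: r should be
  # close to the generator's analytic reliability var(mu)/(var(mu)+sigma^2)
  tr <- screen_truth(sigma = 0.05, n_biased = 0, missing_b_a = 0,
                     missing_b_alpha = 0, seed = 9)
  scr <- simulate_screen(tr)
  keep <- scr$colonies$background == "SpA"
  colsA <- scr$colonies[keep, ]
  rrA <- replicate_reproducibility(colsA, scr$design)
  expect_equal(nrow(scr$design[scr$design$background == "SpA", ]), 576L)
  mu <- tapply(log10(colsA$normalized_size + 1), colsA$cross_id, mean)
  reliability <- var(mu) / (var(mu) + 0.05^2)
  expect_true(all(abs(rrA$r - reliability) < 0.05))
})

test_that("constant replicate vectors give an undefined correlation", {
  libs <- full_libs(2L)
  d <- enumerate_crosses(libs[[1]], libs[[2]])
  dA <- d[d$background == "A", ]
  colonies <- data.frame(cross_id = rep(dA$cross_id, each = 2),
                         replicate = rep(1:2, nrow(dA)),
                         normalized_size = 5)
  expect_warning(rr <- replicate_reproducibility(colonies, d), "undefined")
  expect_true(all(is.na(rr$r)))
})

test_that("a perfectly correlated offset group is shifted down to equal means", {
  cmp <- null_comparison(n_prot = 6L, noise = 0.02, seed = 3)
  x <- cmp$x; y <- cmp$y
  # displace one bait group in y by +0.5 exactly
  g <- y$bait == "q03"
  y$SI[g] <- x$SI[g] + 0.5
  m <- correct_strain_bias(x, y, tagged_side = "a")
  s <- m$strains[m$strains$strain == "q03", ]
  expect_true(s$applied)
  expect_equal(s$side, "y")
  expect_equal(s$shift, -0.5)
  expect_equal(mean(m$y$SI[g]), mean(m$x$SI[g]))
  # correction never increases any value
  expect_true(all(m$x$SI <= x$SI + 1e-12))
  expect_true(all(m$y$SI <= y$SI + 1e-12))
})

test_that("groups failing the correlation gate are left untouched", {
  cmp <- null_comparison(n_prot = 6L, noise = 0.02, seed = 5)
  x <- cmp$x; y <- cmp$y
  g <- y$bait == "q05"
  y$SI[g] <- withr::with_seed(8, sample(y$SI[g]))  # destroy the correlation
  m <- correct_strain_bias(x, y, tagged_side = "a")
  s <- m$strains[m$strains$strain == "q05", ]
  expect_false(s$applied)
  expect_equal(s$shift, 0)
  expect_equal(m$y$SI[g], y$SI[g])
  expect_equal(m$x$SI[g], x$SI[g])
})

test_that("correction is idempotent and improves the pooled correlation under bias", {
  improved <- logical(5)
  for (seed in 1:5) {
    tr <- screen_truth(seed = seed)
    sc <- scored_screen(tr)
    x <- si_subset(sc$si, "SpA")
    y <- si_subset(sc$si, "hybrid2")
    m <- correct_strain_bias(x, y, tagged_side = "a")
    improved[seed] <- m$pooled$r_after > m$pooled$r_before
    m2 <- correct_strain_bias(m$x, m$y, tagged_side = "a")
    expect_equal(m2$x$SI, m$x$SI, tolerance = 1e-10)
    expect_equal(m2$y$SI, m$y$SI, tolerance = 1e-10)
    expect_true(all(m$x$SI <= x$SI + 1e-12))
    expect_true(all(m$y$SI <= y$SI + 1e-12))
  }
  expect_true(all(improved))
})

test_that("small strain groups are skipped with a warning", {
  cmp <- null_comparison(n_prot = 4L, seed = 6)
  x <- cmp$x; y <- cmp$y
  keep <- !(x$bait == "q01" & x$prey %in% c("q01", "q02"))
  x <- x[keep, ]; y <- y[keep, ]
  class(x) <- class(cmp$x); class(y) <- class(cmp$y)
  expect_warning(m <- correct_strain_bias(x, y, tagged_side = "a",
                                          min_group = 3L),
                 "skipped")
  expect_false(m$strains$applied[m$strains$strain == "q01"])
})

test_that("the threshold is the maximum among-complex value", {
  si <- make_si(data.frame(bait = c("a", "b", "c"), prey = c("x", "y", "z"),
                           background = "bg", SI = c(1.0, 1.2, 1.38),
                           class = "SA"))
  th <- estimate_threshold(si, "bg")
  expect_equal(th$t, 1.38)
  expect_equal(th$n_SA, 3L)
  si$class <- "SW"
  expect_error(estimate_threshold(si, "bg"), "no among-complex")
})

test_that("calling uses any orientation above t and reports support", {
  si <- make_si(data.frame(bait = c("p1", "p2", "p3", "p4", "p5", "p6"),
                           prey = c("p2", "p1", "p4", "p3", "p6", "p5"),
                           background = "bg",
                           SI = c(1.5, 1.6, 1.5, 1.2, 1.1, 1.3)))
  calls <- call_interactions(si, 1.4, background = "bg")
  r12 <- calls[calls$protein1 == "p1", ]
  expect_true(r12$called)
  expect_equal(r12$support, "reciprocal")
  r34 <- calls[calls$protein1 == "p3", ]
  expect_true(r34$called)
  expect_equal(r34$support, "single_orientation")
  r56 <- calls[calls$protein1 == "p5", ]
  expect_false(r56$called)
  # homomeric pair: single cross, support homomeric
  sih <- make_si(data.frame(bait = "p7", prey = "p7", background = "bg",
                            SI = 2.0))
  ch <- call_interactions(sih, 1.4, background = "bg")
  expect_true(ch$called)
  expect_equal(ch$support, "homomeric")
})

test_that("calling is monotone in the threshold", {
  tr <- screen_truth(seed = 12)
  sc <- scored_screen(tr)
  siA <- si_subset(sc$si, "SpA")
  ts <- seq(0.8, 2.5, by = 0.1)
  n_called <- vapply(ts, function(t)
    sum(call_interactions(siA, t, background = "SpA")$called), numeric(1))
  expect_true(all(diff(n_called) <= 0))
})
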