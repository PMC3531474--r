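test_that("cross enumeration matches nested-loop counting on random libraries", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      nA <- sample(2:6, 1); nB <- sample(2:6, 1)
      libA <- strain_library("A", sprintf("p%02d", 1:nA),
                             available_a = sample(c(TRUE, FALSE), nA, TRUE, c(.8, .2)),
                             available_alpha = sample(c(TRUE, FALSE), nA, TRUE, c(.8, .2)))
      libB <- strain_library("B", sprintf("p%02d", 1:nB),
                             available_a = sample(c(TRUE, FALSE), nB, TRUE, c(.8, .2)),
                             available_alpha = sample(c(TRUE, FALSE), nB, TRUE, c(.8, .2)))
    })
    if (sum(libA$available[libA$mating_type == "a"]) +
        sum(libB$available[libB$mating_type == "a"]) == 0) next
    # brute-force oracle: loop over every strain pair
    strains <- rbind(as.data.frame(libA), as.data.frame(libB))
    n_oracle <- 0L
    for (i in seq_len(nrow(strains))) for (j in seq_len(nrow(strains))) {
      if (strains$mating_type[i] == "a" && strains$mating_type[j] == "alpha" &&
          strains$available[i] && strains$available[j])
        n_oracle <- n_oracle + 1L
    }
    if (n_oracle == 0L) {
      expect_error(enumerate_crosses(libA, libB), "no strains")
    } else {
      d <- enumerate_crosses(libA, libB)
      expect_identical(nrow(d), n_oracle)
      n_baits <- sum(strains$available & strains$mating_type == "a")
      n_preys <- sum(strains$available & strains$mating_type == "alpha")
      expect_identical(nrow(d), n_baits * n_preys)
    }
  }
})

test_that("one protein per library gives one cross per background", {
  libs <- full_libs(1L)
  d <- enumerate_crosses(libs[[1]], libs[[2]])
  expect_equal(nrow(d), 4L)
  expect_setequal(d$background, c("A", "B", "hybrid1", "hybrid2"))
  # hybrid naming convention: hybrid1 = speciesA MATa x speciesB MATalpha
  h1 <- d[d$background == "hybrid1", ]
  expect_equal(h1$bait_species, "A")
  expect_equal(h1$prey_species, "B")
})

test_that("empty or unavailable libraries are rejected", {
  expect_error(strain_library("A", character()), "no strains")
  libA <- strain_library("A", "p1", available_a = FALSE, available_alpha = FALSE)
  libB <- strain_library("B", "p1", available_a = FALSE, available_alpha = FALSE)
  expect_error(enumerate_crosses(libA, libB), "no strains")
})

test_that("testability codes follow the S/NR/R rules", {
  libs <- full_libs(1L)
  tt <- summarize_testability(enumerate_crosses(libs[[1]], libs[[2]]))
  expect_true(all(tt$code == "S"))
  expect_equal(sum(tt$code == "S"), 4L)  # one homomeric pair per background

  # fully-available 24-protein design: 276 R + 24 S pairs per background
  libs24 <- full_libs(24L)
  tt24 <- summarize_testability(enumerate_crosses(libs24[[1]], libs24[[2]]))
  for (bg in unique(tt24$background)) {
    expect_equal(sum(tt24$code == "R" & tt24$background == bg), 276L)
    expect_equal(sum(tt24$code == "S" & tt24$background == bg), 24L)
  }
})

test_that("removing a MATalpha strain turns its R pairs into NR and keeps S fixed", {
  for (seed in 1:3) {
    n <- 5L
    prots <- sprintf("p%02d", 1:n)
    drop <- withr::with_seed(seed, sample(n, 1))
    libA_full <- strain_library("A", prots)
    libA_cut <- strain_library("A", prots,
                               available_alpha = seq_len(n) != drop)
    libB <- strain_library("B", prots)
    tt_full <- summarize_testability(enumerate_crosses(libA_full, libB))
    tt_cut <- summarize_testability(enumerate_crosses(libA_cut, libB))
    for (bg in unique(tt_full$background)) {
      f <- tt_full[tt_full$background == bg, ]
      c_ <- tt_cut[tt_cut$background == bg, ]
      # every pair that changed code involves the dropped protein, and
      # heteromeric changes are exactly R -> NR; the S code of every
      # other protein's homomeric pair is untouched
      changed <- which(f$code != c_$code)
      expect_true(all(f$protein1[changed] == prots[drop] |
                      f$protein2[changed] == prots[drop]))
      hetero <- changed[f$protein1[changed] != f$protein2[changed]]
      expect_true(all(f$code[hetero] == "R" & c_$code[hetero] == "NR"))
      others <- f$protein1 == f$protein2 & f$protein1 != prots[drop]
      expect_identical(c_$code[others], f$code[others])
    }
  }
})

test_that("plate layout fills a 1536 array with 1152 colonies and 384 borders", {
  libs <- full_libs(24L)
  d <- enumerate_crosses(libs[[1]], libs[[2]])
  dA <- d[d$background == "A", ]
  attributes(dA)[c("species_a", "species_b", "proteins", "class")] <-
    attributes(d)[c("species_a", "species_b", "proteins", "class")]
  lay <- layout_plates(dA, grid = c(32, 48), baits_per_plate = 24,
                       preys_per_plate = 16, reps = 3, seed = 11)
  p1 <- lay[lay$plate == 1, ]
  expect_equal(nrow(p1), 1536L)
  expect_equal(sum(p1$role == "cross"), 1152L)
  expect_equal(sum(p1$role == "BORDER"), 384L)
  expect_true(all(table(p1$cross_id[p1$role == "cross"]) == 3L))
})

test_that("layouts are deterministic in the seed and replicates never touch", {
  libs <- full_libs(6L)
  d <- enumerate_crosses(libs[[1]], libs[[2]])
  lay1 <- layout_plates(d, grid = c(12, 12), baits_per_plate = 6,
                        preys_per_plate = 6, reps = 3, seed = 5)
  lay2 <- layout_plates(d, grid = c(12, 12), baits_per_plate = 6,
                        preys_per_plate = 6, reps = 3, seed = 5)
  expect_identical(lay1, lay2)
  lay3 <- layout_plates(d, grid = c(12, 12), baits_per_plate = 6,
                        preys_per_plate = 6, reps = 3, seed = 6)
  expect_false(identical(lay1$cross_id, lay3$cross_id))

  # exhaustive 8-neighbour scan: no two replicates of one cross adjacent
  asn <- lay1[lay1$role == "cross", ]
  for (p in unique(asn$plate)) {
    pp <- asn[asn$plate == p, ]
    for (id in unique(pp$cross_id)) {
      pos <- pp[pp$cross_id == id, c("row", "col")]
      for (i in seq_len(nrow(pos) - 1)) for (j in seq(i + 1, nrow(pos))) {
        expect_false(abs(pos$row[i] - pos$row[j]) <= 1 &&
                     abs(pos$col[i] - pos$col[j]) <= 1)
      }
    }
  }
})

test_that("layout preserves the design multiset and rejects impossible grids", {
  libs <- full_libs(5L)
  d <- enumerate_crosses(libs[[1]], libs[[2]])
  lay <- layout_plates(d, grid = c(10, 10), baits_per_plate = 5,
                       preys_per_plate = 5, reps = 3, seed = 2)
  asn <- lay[lay$role == "cross", ]
  expect_equal(sort(asn$cross_id), sort(rep(d$cross_id, 3)))
  expect_error(
    layout_plates(d, grid = c(4, 4), baits_per_plate = 5,
                  preys_per_plate = 5, reps = 3),
    "capacity")
})

test_that("strain libraries round-trip through TSV", {
  libs <- screen_libs()
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(libs[[2]]), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  re <- read_strain_library(tsv)
  expect_equal(as.data.frame(re)[order(re$strain), ],
               as.data.frame(libs[[2]])[order(libs[[2]]$strain), ],
               ignore_attr = TRUE)
})
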