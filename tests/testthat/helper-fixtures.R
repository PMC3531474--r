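# Shared fixture builders for the test suite.

# Full-availability libraries for two species over the same proteins.
full_libs <- function(n = 4L, species = c("A", "B")) {
  prots <- sprintf("p%02d", seq_len(n))
  list(strain_library(species[1L], prots),
       strain_library(species[2L], prots))
}

# Libraries matching the screen's strain availability: species A complete
# (24 MATa + 24 MATalpha), species B missing 1 MATa and 7 MATalpha.
screen_libs <- function() {
  prots <- sprintf("p%02d", 1:24)
  list(strain_library("Scer", prots),
       strain_library("Skud", prots,
                      available_a = c(rep(TRUE, 23), FALSE),
                      available_alpha = c(rep(TRUE, 17), rep(FALSE, 7))))
}

# Hand-built si_table from a data.frame with bait, prey, background, SI,
# and optionally class.
make_si <- function(df) {
  if (is.null(df$class)) df$class <- "SW"
  df$cross_id <- paste(df$bait, df$prey, df$background)
  df$n_reps <- 3L
  df$bait_species <- NA_character_
  df$prey_species <- NA_character_
  df <- df[, c("cross_id", "bait", "prey", "bait_species", "prey_species",
               "background", "SI", "n_reps", "class")]
  class(df) <- c("si_table", "data.frame")
  df
}

# Two si_tables forming a null comparison: y = x + N(0, noise), with
# n_prot bait groups crossed against n_prot preys.
null_comparison <- function(n_prot = 24L, noise = 0.05, seed = 1L,
                            spread = 0.6) {
  withr::with_seed(seed, {
    prots <- sprintf("q%02d", seq_len(n_prot))
    g <- expand.grid(bait = prots, prey = prots, stringsAsFactors = FALSE)
    base <- 1 + abs(stats::rnorm(nrow(g), 0, spread))
    x <- make_si(data.frame(g, background = "bgX", SI = base))
    y <- make_si(data.frame(g, background = "bgY",
                            SI = base + stats::rnorm(nrow(g), 0, noise)))
    list(x = x, y = y)
  })
}

# Deterministic synthetic screen scored end to end for one background.
scored_screen <- function(truth) {
  scr <- simulate_screen(truth)
  si <- compute_si(scr$colonies, scr$design, complexes = truth$complexes)
  list(screen = scr, si = si)
}

si_subset <- function(si, bg) {
  out <- si[si$background == bg, ]
  class(out) <- class(si)
  out
}
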