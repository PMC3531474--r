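#' Ground truth for a synthetic two-species interaction screen
#'
#' Defines the generating model of a complete DHFR-PCA-style screen:
#' two protein complexes whose within-complex pairs may truly interact,
#' a log10 background growth level, per-edge signal strengths above
#' background, additive per-strain mating-type biases on the log scale,
#' replicate noise, and missing strains. Hybrid backgrounds share the
#' parental edge set except for explicitly planted gains and losses.
#'
#' The defaults emulate the screen the pipeline was built around: 24
#' proteins in two complexes (15 + 9), two species with species B
#' missing 1 MATa and 7 MATalpha strains, 40 true within-complex edges
#' with strengths 0.6-2.0 log10 units above a background of 1.0,
#' replicate noise of 0.1 log10 units, and 2 bait-side strains biased by
#' -0.4 log10 units.
#'
#' @param species Two species identifiers.
#' @param complexes Named character vector protein -> complex (default:
#'   15 `npc*` + 9 `pol*` proteins in complexes `"NPC"`, `"RNApII"`).
#' @param n_edges Number of true heteromeric within-complex edges.
#' @param b0 Background log10 signal level.
#' @param strength_range Range of edge strengths (log10 units above
#'   `b0`).
#' @param sigma Replicate noise standard deviation, log10 units.
#' @param n_biased Number of biased MATa strains (drawn across both
#'   species).
#' @param bias Additive log10 offset of biased strains (negative:
#'   depressed signal).
#' @param missing_b_a,missing_b_alpha How many species-B MATa / MATalpha
#'   strains are unavailable (the last proteins in order).
#' @param planted_loss,planted_gain Optional `data.frame`s
#'   (`background`, `protein1`, `protein2`) removing/adding edges in
#'   single backgrounds; gains use the mean strength.
#' @param seed Integer seed driving every random choice.
#' @return A list of class `screen_truth`.
#' @export
screen_truth <- function(species = c("SpA", "SpB"),
                         complexes = default_complexes(),
                         n_edges = 40L, b0 = 1.0,
                         strength_range = c(0.6, 2.0), sigma = 0.1,
                         n_biased = 2L, bias = -0.4,
                         missing_b_a = 1L, missing_b_alpha = 7L,
                         planted_loss = NULL, planted_gain = NULL,
                         seed = 1L) {
  stopifnot(length(species) == 2L, sigma >= 0, all(strength_range > 0))
  proteins <- names(complexes)
  within_pairs <- do.call(rbind, lapply(split(proteins, complexes), function(p) {
    if (length(p) < 2L) return(NULL)
    cmb <- utils::combn(sort(p), 2L)
    data.frame(protein1 = cmb[1L, ], protein2 = cmb[2L, ],
               stringsAsFactors = FALSE)
  }))
  if (n_edges > nrow(within_pairs))
    stop("more edges requested than within-complex pairs")
  truth <- withr::with_seed(seed, {
    idx <- sample.int(nrow(within_pairs), n_edges)
    edges <- within_pairs[idx, ]
    edges$strength <- stats::runif(n_edges, strength_range[1L], strength_range[2L])
    rownames(edges) <- NULL
    mata_strains <- c(paste(species[1L], proteins, "a", sep = ":"),
                      paste(species[2L], proteins, "a", sep = ":"))
    biased <- if (n_biased > 0L) sample(mata_strains, n_biased) else character()
    list(edges = edges, biased = biased)
  })
  biases <- stats::setNames(rep(bias, length(truth$biased)), truth$biased)
  missing <- c(
    if (missing_b_a > 0L)
      paste(species[2L], utils::tail(proteins, missing_b_a), "a", sep = ":"),
    if (missing_b_alpha > 0L)
      paste(species[2L], utils::tail(proteins, missing_b_alpha), "alpha", sep = ":"))
  backgrounds <- c(species, "hybrid1", "hybrid2")
  ekey <- paste(truth$edges$protein1, truth$edges$protein2)
  edge_sets <- stats::setNames(rep(list(ekey), 4L), backgrounds)
  strengths <- stats::setNames(truth$edges$strength, ekey)
  if (!is.null(planted_loss)) {
    for (k in seq_len(nrow(planted_loss))) {
      bk <- planted_loss$background[k]
      key <- paste(pmin(planted_loss$protein1[k], planted_loss$protein2[k]),
                   pmax(planted_loss$protein1[k], planted_loss$protein2[k]))
      edge_sets[[bk]] <- setdiff(edge_sets[[bk]], key)
    }
  }
  if (!is.null(planted_gain)) {
    for (k in seq_len(nrow(planted_gain))) {
      bk <- planted_gain$background[k]
      key <- paste(pmin(planted_gain$protein1[k], planted_gain$protein2[k]),
                   pmax(planted_gain$protein1[k], planted_gain$protein2[k]))
      edge_sets[[bk]] <- union(edge_sets[[bk]], key)
      if (!key %in% names(strengths))
        strengths[key] <- mean(strength_range)
    }
  }
  structure(list(species = species, complexes = complexes,
                 proteins = proteins, edges = truth$edges,
                 edge_sets = edge_sets, strengths = strengths,
                 b0 = b0, sigma = sigma, biases = biases,
                 missing = missing, seed = seed),
            class = "screen_truth")
}

#' Default two-complex protein set (15 + 9 subunits)
#' @return Named character vector protein -> complex.
#' @export
default_complexes <- function() {
  stats::setNames(c(rep("NPC", 15L), rep("RNApII", 9L)),
                  c(sprintf("npc%02d", 1:15), sprintf("pol%02d", 1:9)))
}

#' Strain libraries implied by a screen truth
#'
#' @param truth A `screen_truth`.
#' @return List of two `strain_library` objects honouring the truth's
#'   missing-strain mask.
#' @export
truth_libraries <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  lapply(truth$species, function(sp) {
    strain_library(sp, truth$proteins,
      available_a = !(paste(sp, truth$proteins, "a", sep = ":") %in% truth$missing),
      available_alpha = !(paste(sp, truth$proteins, "alpha", sep = ":") %in% truth$missing))
  })
}

#' True edges testable in one background of a design
#'
#' @param truth A `screen_truth`.
#' @param design A `cross_design`.
#' @param background Background identifier.
#' @return Character vector of `"protein1 protein2"` keys (sorted pairs)
#'   of true edges with at least one cross in the design.
#' @export
testable_true_edges <- function(truth, design, background) {
  d <- design[design$background == background, ]
  tested <- unique(paste(pmin(d$bait, d$prey), pmax(d$bait, d$prey)))
  intersect(truth$edge_sets[[background]], tested)
}

#' Simulate replicate colony measurements for a whole screen
#'
#' Expected log10 signal of a cross is `b0 + strength (0 for non-edges)
#' + bias(bait strain) + bias(prey strain)`; each replicate adds
#' independent Gaussian noise of sd `sigma` on the log scale
#' (multiplicative on colony sizes), and the colony size is
#' `round(10^signal)` pixels. Deterministic for a fixed truth seed.
#' Simulated plates share one reference scale (no plate effects), so
#' `normalized_size` equals `raw_size`.
#'
#' @param truth A `screen_truth`.
#' @param design A `cross_design`; defaults to enumerating the truth's
#'   libraries.
#' @param reps Replicates per cross (default 3).
#' @return A list of class `simulated_screen`: `colonies` (a
#'   `colony_table` with `cross_id`, `replicate`, `background`,
#'   `raw_size`, `normalized_size`), `design`, `truth`.
#' @export
simulate_screen <- function(truth, design = NULL, reps = 3L) {
  stopifnot(inherits(truth, "screen_truth"))
  if (is.null(design)) {
    libs <- truth_libraries(truth)
    design <- enumerate_crosses(libs[[1L]], libs[[2L]])
  }
  bad <- setdiff(unique(c(design$bait, design$prey)), truth$proteins)
  if (length(bad) > 0L)
    stop("design references proteins unknown to the truth: ",
         paste(bad, collapse = ", "))
  key <- paste(pmin(design$bait, design$prey), pmax(design$bait, design$prey))
  strength <- numeric(nrow(design))
  for (bg in names(truth$edge_sets)) {
    i <- design$background == bg & key %in% truth$edge_sets[[bg]]
    strength[i] <- truth$strengths[key[i]]
  }
  bias_of <- function(strain) {
    b <- truth$biases[strain]
    ifelse(is.na(b), 0, b)
  }
  mu <- truth$b0 + strength + bias_of(design$bait_strain) +
        bias_of(design$prey_strain)
  colonies <- withr::with_seed(truth$seed + 1L, {
    n <- nrow(design) * reps
    eps <- stats::rnorm(n, 0, truth$sigma)
    data.frame(
      plate = rep(design$background, each = reps),
      cross_id = rep(design$cross_id, each = reps),
      replicate = rep(seq_len(reps), times = nrow(design)),
      background = rep(design$background, each = reps),
      raw_size = round(10^(rep(mu, each = reps) + eps)),
      stringsAsFactors = FALSE)
  })
  colonies$normalized_size <- colonies$raw_size
  class(colonies) <- c("colony_table", "data.frame")
  structure(list(colonies = colonies, design = design, truth = truth),
            class = "simulated_screen")
}

# lattice-disk area for radius r
.disk_area <- function(r) {
  if (r <= 0) return(0L)
  R <- ceiling(r)
  dx <- seq.int(-R, R)
  sum(outer(dx^2, dx^2, "+") <= r^2)
}

# radius whose rasterized area is closest to the target size
.disk_radius <- function(size, rmax) {
  if (size <= 0) return(0)
  cand <- seq(0.5, rmax, by = 0.1)
  areas <- vapply(cand, .disk_area, numeric(1))
  if (size > max(areas)) return(NA_real_)
  cand[which.min(abs(areas - size))]
}

#' Render simulated colonies as plate images
#'
#' Each assigned layout position receives a filled disk whose pixel
#' area is as close as the integer lattice allows to the simulated
#' colony size; running [quantify_plate()] on the rendering recovers the
#' sizes within the disk-rasterization tolerance (`4*ceiling(r) + 4`
#' pixels).
#'
#' @param screen A `simulated_screen`.
#' @param layout A `plate_layout` covering the screen's crosses.
#' @param pitch Cell pitch in pixels.
#' @param fg,bg Foreground / background intensities.
#' @return A list of `plate_image` objects, one per plate in the
#'   layout, named by plate number.
#' @export
render_plates <- function(screen, layout, pitch = 40L, fg = 1, bg = 0) {
  stopifnot(inherits(screen, "simulated_screen"),
            inherits(layout, "plate_layout"))
  grid <- attr(layout, "grid")
  c0 <- ceiling(pitch / 2)                   # integer cell-center offset
  rmax <- min(c0 - 1L, pitch - c0)
  col_key <- paste(screen$colonies$cross_id, screen$colonies$replicate)
  images <- list()
  for (p in unique(layout$plate)) {
    lay <- layout[layout$plate == p, ]
    px <- matrix(bg, nrow = grid[1L] * pitch, ncol = grid[2L] * pitch)
    for (k in which(lay$role == "cross")) {
      size <- screen$colonies$raw_size[
        match(paste(lay$cross_id[k], lay$replicate[k]), col_key)]
      if (is.na(size)) next
      if (size == 0) next
      r <- .disk_radius(size, rmax)
      if (is.na(r))
        stop("colony too large for cell pitch: ", lay$cross_id[k],
             " (size ", size, ")")
      cy <- (lay$row[k] - 1L) * pitch + c0
      cx <- (lay$col[k] - 1L) * pitch + c0
      R <- ceiling(r)
      d2 <- seq.int(-R, R)^2
      mask <- outer(d2, d2, "+") <= r^2
      px[cy + seq.int(-R, R), cx + seq.int(-R, R)][mask] <- fg
    }
    images[[as.character(p)]] <- plate_image(px, rows = grid[1L],
                                             cols = grid[2L], pitch = pitch)
  }
  images
}

#' Simulate a three-taxon alignment with planted events
#'
#' Plants a known set of focal-only substitutions (only the focal taxon
#' derived), shared substitutions (focal plus one other taxon derived,
#' so not lineage-specific), and gap blocks, on a random ancestral
#' amino-acid sequence.
#'
#' @param length Alignment length in columns.
#' @param n_focal_changes,n_shared_changes Numbers of planted
#'   substitutions.
#' @param indels List of `list(start =, length =, gap_in =)` blocks;
#'   `gap_in` names the taxa carrying the gap.
#' @param taxa Three taxon names; the first is the focal taxon.
#' @param seed Integer seed.
#' @return A list of class `simulated_msa`: `msa` (an `msa_profile`),
#'   `focal_changes` (`data.frame` column/from/to), `shared_changes`,
#'   `indels`.
#' @export
simulate_msa <- function(length, n_focal_changes = 5L, n_shared_changes = 2L,
                         indels = list(), taxa = c("focal", "taxonB", "taxonC"),
                         seed = 1L) {
  stopifnot(length(taxa) == 3L)
  aa <- names(polarity_classes())
  indel_cols <- integer()
  for (b in indels) {
    cols <- seq.int(b$start, b$start + b$length - 1L)
    if (any(cols %in% indel_cols) || any(cols > length) || b$start < 1L)
      stop("overlapping planted events")
    if (!all(b$gap_in %in% taxa)) stop("unknown taxon in indel block")
    indel_cols <- c(indel_cols, cols)
  }
  free <- setdiff(seq_len(length), indel_cols)
  if (n_focal_changes + n_shared_changes > length(free))
    stop("overlapping planted events")
  out <- withr::with_seed(seed, {
    anc <- sample(aa, length, replace = TRUE)
    pos <- sample(free, n_focal_changes + n_shared_changes)
    focal_pos <- sort(pos[seq_len(n_focal_changes)])
    shared_pos <- sort(pos[-seq_len(n_focal_changes)])
    derive <- function(res) vapply(res, function(x) sample(setdiff(aa, x), 1L), "")
    s <- rbind(anc, anc, anc)
    rownames(s) <- taxa
    if (n_focal_changes > 0L)
      s[1L, focal_pos] <- derive(anc[focal_pos])
    if (n_shared_changes > 0L) {
      der <- derive(anc[shared_pos])
      s[1L, shared_pos] <- der
      s[2L, shared_pos] <- der
    }
    list(s = s, focal_pos = focal_pos, shared_pos = shared_pos, anc = anc)
  })
  s <- out$s
  for (b in indels) {
    cols <- seq.int(b$start, b$start + b$length - 1L)
    s[b$gap_in, cols] <- "-"
  }
  msa <- msa_profile(apply(s, 1L, paste, collapse = ""))
  structure(list(
    msa = msa,
    focal_changes = data.frame(column = out$focal_pos,
                               from = out$anc[out$focal_pos],
                               to = s[1L, out$focal_pos],
                               stringsAsFactors = FALSE),
    shared_changes = data.frame(column = out$shared_pos,
                                from = out$anc[out$shared_pos],
                                to = s[1L, out$shared_pos],
                                stringsAsFactors = FALSE),
    indels = indels, taxa = taxa, seed = seed
  ), class = "simulated_msa")
}
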