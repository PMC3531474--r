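#' Build a tagged-strain library for one species
#'
#' A DHFR-PCA screen crosses MATa strains, carrying the F[1,2] fragment
#' fused to a protein of interest, with MATalpha strains carrying the F[3]
#' fragment. A strain library records which tagged strains of one species
#' exist and whether they were successfully constructed (available).
#'
#' @param species Species identifier (e.g. `"Scer"`).
#' @param proteins Character vector of protein identifiers tagged in this
#'   species.
#' @param available_a,available_alpha Logical vectors (recycled) stating,
#'   per protein, whether the MATa (F\[1,2\]) and MATalpha (F\[3\]) strain
#'   was obtained. Defaults to all available.
#' @return A `data.frame` of class `strain_library` with columns
#'   `species`, `protein`, `mating_type`, `fragment`, `available`.
#'   The mating type determines the fragment: MATa strains carry F12,
#'   MATalpha strains carry F3.
#' @examples
#' lib <- strain_library("Scer", paste0("p", 1:4))
#' subset(lib, mating_type == "a")
#' @export
strain_library <- function(species, proteins,
                           available_a = TRUE, available_alpha = TRUE) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  proteins <- as.character(proteins)
  if (length(proteins) == 0L) stop("no strains")
  if (anyDuplicated(proteins)) stop("duplicated protein identifiers")
  lib <- rbind(
    data.frame(species = species, protein = proteins, mating_type = "a",
               fragment = "F12",
               available = rep_len(as.logical(available_a), length(proteins)),
               stringsAsFactors = FALSE),
    data.frame(species = species, protein = proteins, mating_type = "alpha",
               fragment = "F3",
               available = rep_len(as.logical(available_alpha), length(proteins)),
               stringsAsFactors = FALSE)
  )
  lib$strain <- paste(lib$species, lib$protein, lib$mating_type, sep = ":")
  class(lib) <- c("strain_library", "data.frame")
  lib
}

#' Read a strain library from TSV
#'
#' Expects columns `species`, `protein`, `mating_type`, `available`.
#'
#' @param path Path to a tab-separated file.
#' @return A `strain_library` (see [strain_library()]).
#' @export
read_strain_library <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "protein", "mating_type", "available")
  if (!all(need %in% names(d)))
    stop("strain library TSV must have columns: ", paste(need, collapse = ", "))
  sp <- unique(d$species)
  if (length(sp) != 1L) stop("one species per library file")
  da <- d[d$mating_type == "a", ]
  dalpha <- d[d$mating_type == "alpha", ]
  prots <- union(da$protein, dalpha$protein)
  strain_library(sp, prots,
    available_a = prots %in% da$protein[da$available],
    available_alpha = prots %in% dalpha$protein[dalpha$available])
}

#' Enumerate all testable crosses between two species libraries
#'
#' Every available MATa strain (either species) is crossed with every
#' available MATalpha strain (either species), producing diploids in four
#' backgrounds: the two parental species and the two reciprocal hybrids.
#' Hybrid 1 is speciesA-MATa x speciesB-MATalpha; hybrid 2 is the reverse.
#'
#' @param libA,libB `strain_library` objects for the two species.
#' @return A `data.frame` of class `cross_design` with one row per cross:
#'   `cross_id`, `bait` / `prey` (protein), `bait_species`, `prey_species`,
#'   `bait_strain`, `prey_strain`, `background`. Attributes `species_a`,
#'   `species_b` and `proteins` record the design universe.
#' @examples
#' a <- strain_library("A", c("p1", "p2"))
#' b <- strain_library("B", c("p1", "p2"))
#' table(enumerate_crosses(a, b)$background)
#' @export
enumerate_crosses <- function(libA, libB) {
  for (lib in list(libA, libB)) {
    if (!inherits(lib, "strain_library") || nrow(lib) == 0L) stop("no strains")
  }
  spA <- libA$species[1L]
  spB <- libB$species[1L]
  if (spA == spB) stop("libraries must come from two different species")
  all_strains <- rbind(as.data.frame(libA), as.data.frame(libB))
  baits <- all_strains[all_strains$mating_type == "a" & all_strains$available, ]
  preys <- all_strains[all_strains$mating_type == "alpha" & all_strains$available, ]
  if (nrow(baits) == 0L || nrow(preys) == 0L) stop("no strains")
  idx <- expand.grid(bait = seq_len(nrow(baits)), prey = seq_len(nrow(preys)))
  design <- data.frame(
    bait = baits$protein[idx$bait],
    prey = preys$protein[idx$prey],
    bait_species = baits$species[idx$bait],
    prey_species = preys$species[idx$prey],
    bait_strain = baits$strain[idx$bait],
    prey_strain = preys$strain[idx$prey],
    stringsAsFactors = FALSE
  )
  design$background <- ifelse(design$bait_species == spA,
    ifelse(design$prey_species == spA, spA, "hybrid1"),
    ifelse(design$prey_species == spB, spB, "hybrid2"))
  design$cross_id <- paste(design$bait_strain, design$prey_strain, sep = " x ")
  design <- design[order(design$background, design$bait, design$prey), ]
  rownames(design) <- NULL
  attr(design, "species_a") <- spA
  attr(design, "species_b") <- spB
  attr(design, "proteins") <- sort(unique(c(libA$protein, libB$protein)))
  class(design) <- c("cross_design", "data.frame")
  design
}

#' Classify protein-pair testability per background
#'
#' Each protein pair in each background is coded `S` (homomeric, P1-P1),
#' `R` (reciprocal: both tag orientations P1-bait x P2-prey and
#' P2-bait x P1-prey exist in that background), `NR` (exactly one
#' orientation), or `untestable` (no orientation; e.g. a missing strain).
#'
#' @param design A `cross_design` from [enumerate_crosses()].
#' @param proteins Optional character vector of the protein universe;
#'   defaults to the design's `proteins` attribute.
#' @return A `data.frame` with columns `background`, `protein1`,
#'   `protein2` (sorted within pair), `code`, `n_crosses`.
#' @examples
#' a <- strain_library("A", paste0("p", 1:3))
#' b <- strain_library("B", paste0("p", 1:3))
#' tab <- summarize_testability(enumerate_crosses(a, b))
#' table(tab$background, tab$code)
#' @export
summarize_testability <- function(design, proteins = NULL) {
  stopifnot(inherits(design, "cross_design"))
  if (is.null(proteins)) proteins <- attr(design, "proteins")
  proteins <- sort(unique(proteins))
  pairs <- expand.grid(i = seq_along(proteins), j = seq_along(proteins))
  pairs <- pairs[pairs$i <= pairs$j, ]
  out <- lapply(unique(design$background), function(bg) {
    d <- design[design$background == bg, ]
    key <- paste(d$bait, d$prey)
    n1 <- vapply(seq_len(nrow(pairs)), function(k) {
      sum(key == paste(proteins[pairs$i[k]], proteins[pairs$j[k]]))
    }, integer(1))
    n2 <- vapply(seq_len(nrow(pairs)), function(k) {
      if (pairs$i[k] == pairs$j[k]) 0L
      else sum(key == paste(proteins[pairs$j[k]], proteins[pairs$i[k]]))
    }, integer(1))
    homo <- pairs$i == pairs$j
    code <- ifelse(homo,
      ifelse(n1 > 0L, "S", "untestable"),
      ifelse(n1 > 0L & n2 > 0L, "R",
        ifelse(n1 + n2 > 0L, "NR", "untestable")))
    data.frame(background = bg,
               protein1 = proteins[pairs$i], protein2 = proteins[pairs$j],
               code = code, n_crosses = n1 + n2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 8-neighbourhood adjacency between two grid positions
.adjacent8 <- function(r1, c1, r2, c2) {
  abs(r1 - r2) <= 1L & abs(c1 - c2) <= 1L & !(r1 == r2 & c1 == c2)
}

#' Lay crosses out on colony-array plates with non-adjacent replicates
#'
#' Crosses are grouped onto plates by bait and prey blocks (e.g. 24 baits
#' x 16 preys per 32x48 plate), then each cross is pinned at `reps`
#' random positions, rejecting placements where two replicates of the
#' same cross touch (8-neighbourhood). Unused positions are BORDER and
#' carry no cross.
#'
#' @param design A `cross_design`.
#' @param grid `c(rows, cols)` of the colony array (default 32 x 48, a
#'   1536 array).
#' @param baits_per_plate,preys_per_plate Block sizes defining plate
#'   composition.
#' @param reps Replicates per cross (default 3).
#' @param seed Integer seed; layouts are deterministic given the seed.
#' @param max_retries Resampling attempts per cross before giving up.
#' @return A `data.frame` of class `plate_layout`: one row per grid
#'   position with `plate`, `row`, `col`, `cross_id`, `replicate`,
#'   `bait`, `prey`, `background`, `role` (`"cross"` or `"BORDER"`).
#' @export
layout_plates <- function(design, grid = c(32L, 48L),
                          baits_per_plate = 24L, preys_per_plate = 16L,
                          reps = 3L, seed = 1L, max_retries = 100L) {
  stopifnot(inherits(design, "cross_design"), length(grid) == 2L)
  rows <- as.integer(grid[1L]); cols <- as.integer(grid[2L])
  if (baits_per_plate * preys_per_plate * reps > rows * cols)
    stop("plate capacity exceeded: ", baits_per_plate * preys_per_plate * reps,
         " positions needed on a ", rows, "x", cols, " grid")
  withr::with_seed(seed, {
    plates <- list()
    plate_no <- 0L
    for (bg in unique(design$background)) {
      d <- design[design$background == bg, ]
      bait_blocks <- split(unique(d$bait_strain),
        ceiling(seq_along(unique(d$bait_strain)) / baits_per_plate))
      prey_blocks <- split(unique(d$prey_strain),
        ceiling(seq_along(unique(d$prey_strain)) / preys_per_plate))
      for (bb in bait_blocks) for (pb in prey_blocks) {
        dd <- d[d$bait_strain %in% bb & d$prey_strain %in% pb, ]
        if (nrow(dd) == 0L) next
        plate_no <- plate_no + 1L
        plates[[plate_no]] <- .layout_one_plate(dd, plate_no, rows, cols,
                                                reps, max_retries)
      }
    }
    layout <- do.call(rbind, plates)
  })
  rownames(layout) <- NULL
  attr(layout, "grid") <- c(rows, cols)
  attr(layout, "reps") <- reps
  attr(layout, "seed") <- seed
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

.layout_one_plate <- function(dd, plate_no, rows, cols, reps, max_retries) {
  n_pos <- rows * cols
  assigned_cross <- rep(NA_character_, n_pos)
  assigned_rep <- rep(NA_integer_, n_pos)
  free <- seq_len(n_pos)
  for (k in sample.int(nrow(dd))) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      pos <- if (length(free) == reps) free else sample(free, reps)
      pr <- ((pos - 1L) %% rows) + 1L
      pc <- ((pos - 1L) %/% rows) + 1L
      clash <- FALSE
      for (i in seq_len(reps - 1L)) for (j in seq(i + 1L, reps)) {
        if (.adjacent8(pr[i], pc[i], pr[j], pc[j])) clash <- TRUE
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place non-adjacent replicates for cross ",
           dd$cross_id[k], " after ", max_retries, " attempts")
    assigned_cross[pos] <- dd$cross_id[k]
    assigned_rep[pos] <- seq_len(reps)
    free <- setdiff(free, pos)
  }
  pos <- seq_len(n_pos)
  m <- match(assigned_cross, dd$cross_id)
  data.frame(
    plate = plate_no,
    row = ((pos - 1L) %% rows) + 1L,
    col = ((pos - 1L) %/% rows) + 1L,
    cross_id = assigned_cross,
    replicate = assigned_rep,
    bait = dd$bait[m], prey = dd$prey[m],
    background = dd$background[m],
    role = ifelse(is.na(assigned_cross), "BORDER", "cross"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cross_design <- function(x, ...) {
  cat("Cross design: ", nrow(x), " crosses (",
      attr(x, "species_a"), ", ", attr(x, "species_b"),
      ", 2 reciprocal hybrids)\n", sep = "")
  print(table(background = x$background))
  invisible(x)
}

#' Write a cross design or plate layout to TSV
#' @param x A `cross_design` or `plate_layout`.
#' @param path Output file path.
#' @export
write_design <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
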