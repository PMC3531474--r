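#' Compute per-cross signal indices (SI) from replicate colonies
#'
#' Triplicate (or `n`-plicate) normalized colony sizes are averaged per
#' cross and the mean is put on the log10 scale:
#' `SI = log10(mean(normalized size) + pseudocount)`.
#'
#' @param colonies A `colony_table` carrying `cross_id`, `replicate` and
#'   `normalized_size` (e.g. from [assign_colonies()] or
#'   [simulate_screen()]).
#' @param design The `cross_design` the colonies were pinned from; any
#'   colony whose `cross_id` is not in the design is an error.
#' @param complexes Optional named character vector mapping protein to
#'   complex; when given, each cross is classed `SW` (bait and prey in
#'   the same complex, a candidate interaction) or `SA` (among-complex,
#'   the background null set).
#' @param pseudocount Added to the mean before the log (default 1), so
#'   all-zero crosses score 0.
#' @return A `data.frame` of class `si_table`: `bait`, `prey`,
#'   `bait_species`, `prey_species`, `background`, `SI`, `n_reps`,
#'   `class`.
#' @export
compute_si <- function(colonies, design, complexes = NULL, pseudocount = 1) {
  stopifnot(is.data.frame(colonies),
            all(c("cross_id", "normalized_size") %in% names(colonies)),
            inherits(design, "cross_design"))
  orphans <- setdiff(unique(colonies$cross_id), design$cross_id)
  if (length(orphans) > 0L)
    stop("colonies with no design entry: ", paste(orphans, collapse = ", "))
  if (any(is.na(colonies$normalized_size)))
    stop("normalized sizes missing; run normalize_plate() first")
  agg <- stats::aggregate(normalized_size ~ cross_id, colonies,
                          function(v) c(mean = mean(v), n = length(v)))
  si <- data.frame(cross_id = agg$cross_id,
                   SI = log10(agg$normalized_size[, "mean"] + pseudocount),
                   n_reps = as.integer(agg$normalized_size[, "n"]),
                   stringsAsFactors = FALSE)
  m <- match(si$cross_id, design$cross_id)
  si$bait <- design$bait[m]
  si$prey <- design$prey[m]
  si$bait_species <- design$bait_species[m]
  si$prey_species <- design$prey_species[m]
  si$background <- design$background[m]
  if (!is.null(complexes)) {
    unknown <- setdiff(unique(c(si$bait, si$prey)), names(complexes))
    if (length(unknown) > 0L)
      stop("proteins without complex assignment: ",
           paste(unknown, collapse = ", "))
    si$class <- ifelse(complexes[si$bait] == complexes[si$prey], "SW", "SA")
  } else {
    si$class <- NA_character_
  }
  si <- si[order(si$background, si$bait, si$prey),
           c("cross_id", "bait", "prey", "bait_species", "prey_species",
             "background", "SI", "n_reps", "class")]
  rownames(si) <- NULL
  class(si) <- c("si_table", "data.frame")
  si
}

#' Replicate reproducibility of log colony sizes
#'
#' Pearson correlation of log10 normalized colony sizes between each
#' pair of replicates (1-2, 1-3, 2-3), per background.
#'
#' @inheritParams compute_si
#' @param pseudocount Added before the log (default 1).
#' @return A `data.frame`: `background`, `rep_i`, `rep_j`, `n`, `r`,
#'   `p`. `r` is `NA` (with a warning) when a replicate vector is
#'   constant.
#' @export
replicate_reproducibility <- function(colonies, design, pseudocount = 1) {
  stopifnot(all(c("cross_id", "replicate", "normalized_size") %in% names(colonies)))
  m <- match(colonies$cross_id, design$cross_id)
  if (anyNA(m)) stop("colonies with no design entry")
  colonies$background <- design$background[m]
  colonies$logsize <- log10(colonies$normalized_size + pseudocount)
  out <- list()
  for (bg in unique(colonies$background)) {
    d <- colonies[colonies$background == bg, ]
    reps <- sort(unique(d$replicate))
    wide <- stats::reshape(d[, c("cross_id", "replicate", "logsize")],
                           idvar = "cross_id", timevar = "replicate",
                           direction = "wide")
    for (i in seq_len(length(reps) - 1L)) for (j in seq(i + 1L, length(reps))) {
      vi <- wide[[paste0("logsize.", reps[i])]]
      vj <- wide[[paste0("logsize.", reps[j])]]
      keep <- stats::complete.cases(vi, vj)
      if (stats::sd(vi[keep]) == 0 || stats::sd(vj[keep]) == 0) {
        warning("constant replicate vector in background ", bg,
                "; correlation undefined")
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(vi[keep], vj[keep])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        background = bg, rep_i = reps[i], rep_j = reps[j],
        n = sum(keep), r = r, p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Correct per-strain mating-type biases between two SI tables
#'
#' Some haploid strains depress (or inflate) the growth signal of every
#' cross they enter, in one mating type only; left uncorrected this
#' masks true interactions or fakes differences between backgrounds.
#' For each protein tagged on `tagged_side`, the SI values shared
#' between the two tables are compared: when the within-strain Pearson
#' correlation is significant (p below `alpha_level`), the side with the
#' HIGHER group mean is shifted down by the mean difference so the group
#' means match. Shifting down (never up) is conservative: it can drop a
#' weak signal into the background but can never promote background to
#' signal. Non-significant groups are left untouched. After the per-
#' group pass, an ordinary least-squares regression of corrected `y` on
#' corrected `x` over all shared crosses supplies the pooled residuals
#' used for divergence testing.
#'
#' @param x,y `si_table`s for the two compared backgrounds (e.g. one
#'   species and one hybrid), sharing crosses keyed by (bait, prey).
#' @param tagged_side `"a"` (group by bait protein) or `"alpha"` (group
#'   by prey protein): the mating type whose strain differs between the
#'   two backgrounds.
#' @param alpha_level Significance gate for the per-strain correlation
#'   (default 0.001).
#' @param min_group Minimum shared crosses per strain group; smaller
#'   groups are skipped with a warning.
#' @param method `"mean_shift"` (default; decrease-only, as described
#'   above) or `"slope"`, which maps the higher-mean side through the
#'   inverse of the within-group regression line (matches slope as well
#'   as mean, but is not decrease-only).
#' @return A list of class `correction_model`: corrected tables `x` and
#'   `y`; `strains` (per group: `n`, `r`, `p`, `applied`, `side`,
#'   `shift`); `shared` (per shared cross: corrected values and pooled
#'   residual); `pooled` (lm coefficients, residual vector, residual sd,
#'   and Pearson r before/after correction); `tagged_side`,
#'   `alpha_level`.
#' @export
correct_strain_bias <- function(x, y, tagged_side = c("a", "alpha"),
                                alpha_level = 0.001, min_group = 3L,
                                method = c("mean_shift", "slope")) {
  tagged_side <- match.arg(tagged_side)
  method <- match.arg(method)
  min_group <- max(as.integer(min_group), 3L)  # cor.test needs >= 3 points
  stopifnot(inherits(x, "si_table"), inherits(y, "si_table"))
  keycols <- c("bait", "prey")
  shared <- merge(as.data.frame(x)[, c(keycols, "SI")],
                  as.data.frame(y)[, c(keycols, "SI")],
                  by = keycols, suffixes = c("_x", "_y"))
  if (nrow(shared) == 0L) stop("no shared crosses between x and y")
  shared$group <- if (tagged_side == "a") shared$bait else shared$prey
  r_before <- stats::cor(shared$SI_x, shared$SI_y)
  shared$SI_x_corr <- shared$SI_x
  shared$SI_y_corr <- shared$SI_y
  strains <- list()
  for (g in sort(unique(shared$group))) {
    i <- shared$group == g
    n <- sum(i)
    if (n < min_group) {
      warning("strain group ", g, " has ", n, " shared crosses (< ",
              min_group, "); skipped")
      strains[[g]] <- data.frame(strain = g, n = n, r = NA_real_,
                                 p = NA_real_, applied = FALSE,
                                 side = NA_character_, shift = 0,
                                 stringsAsFactors = FALSE)
      next
    }
    gx <- shared$SI_x[i]; gy <- shared$SI_y[i]
    if (stats::sd(gx) == 0 || stats::sd(gy) == 0) {
      r <- NA_real_; p <- 1
    } else {
      ct <- stats::cor.test(gx, gy)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    applied <- is.finite(p) && p < alpha_level
    side <- NA_character_; shift <- 0
    if (applied) {
      dmean <- mean(gy) - mean(gx)
      side <- if (dmean > 0) "y" else "x"
      if (method == "mean_shift") {
        shift <- -abs(dmean)
        if (side == "y") shared$SI_y_corr[i] <- gy + shift
        else             shared$SI_x_corr[i] <- gx + shift
      } else {
        # inverse-regression variant: map the higher side onto the lower
        if (side == "y") {
          fit <- stats::lm(gy ~ gx)
          b <- stats::coef(fit)
          shared$SI_y_corr[i] <- (gy - b[1L]) / b[2L]
          shift <- mean(shared$SI_y_corr[i] - gy)
        } else {
          fit <- stats::lm(gx ~ gy)
          b <- stats::coef(fit)
          shared$SI_x_corr[i] <- (gx - b[1L]) / b[2L]
          shift <- mean(shared$SI_x_corr[i] - gx)
        }
      }
      if (abs(shift) < .Machine$double.eps^0.5) {
        applied <- FALSE; side <- NA_character_; shift <- 0
      }
    }
    strains[[g]] <- data.frame(strain = g, n = n, r = r, p = p,
                               applied = applied, side = side,
                               shift = shift, stringsAsFactors = FALSE)
  }
  strains <- do.call(rbind, strains)
  rownames(strains) <- NULL
  fit <- stats::lm(SI_y_corr ~ SI_x_corr, data = shared)
  shared$residual <- stats::residuals(fit)
  r_after <- stats::cor(shared$SI_x_corr, shared$SI_y_corr)

  xc <- x; yc <- y
  kx <- match(paste(x$bait, x$prey), paste(shared$bait, shared$prey))
  ky <- match(paste(y$bait, y$prey), paste(shared$bait, shared$prey))
  xc$SI[!is.na(kx)] <- shared$SI_x_corr[kx[!is.na(kx)]]
  yc$SI[!is.na(ky)] <- shared$SI_y_corr[ky[!is.na(ky)]]

  structure(list(
    x = xc, y = yc,
    strains = strains,
    shared = shared,
    pooled = list(coef = stats::coef(fit),
                  residuals = stats::setNames(shared$residual,
                                              paste(shared$bait, shared$prey)),
                  sigma = stats::sd(shared$residual),
                  r_before = r_before, r_after = r_after),
    tagged_side = tagged_side, alpha_level = alpha_level, method = method
  ), class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("SI bias correction (tagged side: MAT", x$tagged_side, ")\n", sep = "")
  cat("  strain groups: ", nrow(x$strains), " (",
      sum(x$strains$applied), " corrected at alpha = ", x$alpha_level, ")\n",
      sep = "")
  cat(sprintf("  pooled Pearson r: %.3f before, %.3f after correction\n",
              x$pooled$r_before, x$pooled$r_after))
  invisible(x)
}

#' Estimate the interaction-calling threshold from among-complex crosses
#'
#' Crosses between proteins of two unrelated complexes (SA values) are
#' assumed to reflect background colony growth only, so the calling
#' threshold `t` for a background is set to the maximum SA value of that
#' background: by construction no among-complex cross is ever called.
#'
#' @param si An `si_table` with `class` filled in.
#' @param background Which background to estimate for; may be omitted if
#'   the table holds a single background.
#' @return A list of class `threshold_estimate`: `background`, `t`,
#'   `n_SA`.
#' @export
estimate_threshold <- function(si, background = NULL) {
  stopifnot(inherits(si, "si_table"))
  if (is.null(background)) {
    background <- unique(si$background)
    if (length(background) != 1L)
      stop("several backgrounds present; say which one")
  }
  sa <- si$SI[si$background == background & si$class == "SA"]
  sa <- sa[!is.na(sa)]
  if (length(sa) == 0L) stop("no among-complex crosses")
  structure(list(background = background, t = max(sa), n_SA = length(sa)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Threshold t = %.3f (max of %d among-complex SI values, %s)\n",
              x$t, x$n_SA, x$background))
  invisible(x)
}

#' Call protein-protein interactions above the background threshold
#'
#' Within-complex (SW) crosses are collapsed to unordered protein pairs;
#' a pair is called an interaction when any tested tag orientation has
#' SI above the threshold. Support records whether both orientations
#' (`reciprocal`), only one (`single_orientation`), or the single
#' homomeric cross (`homomeric`) carried the call.
#'
#' @param si An `si_table`.
#' @param threshold A `threshold_estimate` for the same background (or a
#'   bare number).
#' @param background Needed only if `si` spans several backgrounds and
#'   `threshold` is a bare number.
#' @return A `data.frame` of class `interaction_calls`, one row per
#'   tested SW pair: `protein1 <= protein2`, `si_fwd` (protein1 as
#'   bait), `si_rev`, `si_max`, `n_orient`, `called`, `support`,
#'   `background`. The threshold is kept as attribute `t`.
#' @export
call_interactions <- function(si, threshold, background = NULL) {
  stopifnot(inherits(si, "si_table"))
  if (inherits(threshold, "threshold_estimate")) {
    background <- threshold$background
    t <- threshold$t
  } else {
    t <- as.numeric(threshold)
    if (is.null(background)) {
      background <- unique(si$background)
      if (length(background) != 1L)
        stop("several backgrounds present; say which one")
    }
  }
  d <- si[si$background == background & si$class == "SW", ]
  if (nrow(d) == 0L) stop("no within-complex crosses in ", background)
  p1 <- pmin(d$bait, d$prey)
  p2 <- pmax(d$bait, d$prey)
  key <- paste(p1, p2)
  out <- lapply(unique(key), function(k) {
    i <- key == k
    fwd <- d$SI[i & d$bait == p1[i][1L]]
    rev <- d$SI[i & d$bait == p2[i][1L] & p1 != p2]
    homo <- p1[i][1L] == p2[i][1L]
    n_above <- sum(c(fwd, rev) > t)
    data.frame(protein1 = p1[i][1L], protein2 = p2[i][1L],
               background = background,
               si_fwd = if (length(fwd)) fwd[1L] else NA_real_,
               si_rev = if (length(rev)) rev[1L] else NA_real_,
               si_max = max(c(fwd, rev)),
               n_orient = sum(i),
               called = n_above >= 1L,
               support = if (homo) "homomeric"
                         else if (n_above >= 2L) "reciprocal"
                         else if (n_above == 1L) "single_orientation"
                         else NA_character_,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$protein1, calls$protein2), ]
  rownames(calls) <- NULL
  attr(calls, "t") <- t
  class(calls) <- c("interaction_calls", "data.frame")
  calls
}
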