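#' Build an interaction network from calls
#'
#' @param calls An `interaction_calls` table (one background).
#' @param species Optional named character vector annotating each
#'   protein node with its species of origin (informative in hybrids).
#' @return A list of class `interaction_network`: `nodes` (protein,
#'   species), `edges` (the calls table), `background`.
#' @export
interaction_network <- function(calls, species = NULL) {
  stopifnot(inherits(calls, "interaction_calls"))
  proteins <- sort(unique(c(calls$protein1, calls$protein2)))
  nodes <- data.frame(protein = proteins,
                      species = if (is.null(species))
                                  rep(NA_character_, length(proteins))
                                else unname(species[proteins]),
                      stringsAsFactors = FALSE)
  t <- attr(calls, "t")
  structure(list(nodes = nodes, edges = as.data.frame(calls),
                 background = if (nrow(calls)) calls$background[1L] else NA_character_,
                 t = if (is.null(t)) NA_real_ else t),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network (", x$background, "): ",
      nrow(x$nodes), " proteins, ", sum(x$edges$called), " called of ",
      nrow(x$edges), " tested pairs (t = ", format(x$t, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' Flag interactions whose signal diverges between two backgrounds
#'
#' Residuals of the pooled post-correction regression are standardized
#' by the pooled residual standard deviation, and each shared cross is
#' flagged at the smallest significance level whose two-sided bound its
#' |standardized residual| exceeds (normal quantiles by default, or the
#' empirical quantiles of the pooled residual set).
#'
#' @param model A `correction_model` from [correct_strain_bias()].
#' @param levels Significance levels, largest first (default
#'   0.05, 0.01, 0.001).
#' @param method `"normal"` (default) or `"empirical"` quantile bounds.
#' @return A `data.frame`: `bait`, `prey`, `residual`, `z`
#'   (standardized), `level` (`"none"` or the smallest exceeded level,
#'   as character).
#' @export
flag_divergent <- function(model, levels = c(0.05, 0.01, 0.001),
                           method = c("normal", "empirical")) {
  stopifnot(inherits(model, "correction_model"))
  method <- match.arg(method)
  res <- model$pooled$residuals
  if (length(res) < 10L) stop("insufficient residual pool")
  levels <- sort(as.numeric(levels), decreasing = TRUE)
  z <- if (model$pooled$sigma > 1e-12) res / model$pooled$sigma
       else rep(0, length(res))
  lev <- rep("none", length(res))
  for (q in levels) {
    bound <- if (method == "normal") stats::qnorm(1 - q / 2)
             else stats::quantile(abs(z), 1 - q, names = FALSE)
    lev[abs(z) > bound] <- as.character(q)
  }
  out <- data.frame(bait = model$shared$bait, prey = model$shared$prey,
                    residual = unname(res), z = unname(z), level = lev,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify edges as shared, background-specific, or untestable
#'
#' Protein pairs tested in both networks (the comparable set) are
#' labelled `shared` when called in both, `A_specific` / `B_specific`
#' when called in exactly one, and `background` when called in neither.
#' Pairs tested in only one network (missing strains) are `untestable`.
#' A specific edge counts as significantly divergent only when the
#' residual analysis also flags it: a sub-threshold difference with an
#' unremarkable residual is not evidence of a gained or lost
#' interaction.
#'
#' @param netA,netB `interaction_network`s called with their own
#'   thresholds.
#' @param flags Optional output of [flag_divergent()] for the same
#'   comparison.
#' @return A `data.frame`: `protein1`, `protein2`, `called_A`,
#'   `called_B`, `status`, `divergence_level`, `significant`.
#' @export
classify_edges <- function(netA, netB, flags = NULL) {
  stopifnot(inherits(netA, "interaction_network"),
            inherits(netB, "interaction_network"))
  ea <- netA$edges; eb <- netB$edges
  keyA <- paste(ea$protein1, ea$protein2)
  keyB <- paste(eb$protein1, eb$protein2)
  all_keys <- sort(union(keyA, keyB))
  ma <- match(all_keys, keyA); mb <- match(all_keys, keyB)
  called_A <- ifelse(is.na(ma), NA, ea$called[ma])
  called_B <- ifelse(is.na(mb), NA, eb$called[mb])
  status <- ifelse(is.na(called_A) | is.na(called_B), "untestable",
            ifelse(called_A & called_B, "shared",
            ifelse(called_A & !called_B, "A_specific",
            ifelse(!called_A & called_B, "B_specific", "background"))))
  lev <- rep("none", length(all_keys))
  if (!is.null(flags)) {
    fk1 <- paste(pmin(flags$bait, flags$prey), pmax(flags$bait, flags$prey))
    for (k in seq_along(all_keys)) {
      fl <- flags$level[fk1 == all_keys[k] & flags$level != "none"]
      if (length(fl) > 0L) lev[k] <- as.character(min(as.numeric(fl)))
    }
  }
  parts <- strsplit(all_keys, " ", fixed = TRUE)
  out <- data.frame(
    protein1 = vapply(parts, `[`, "", 1L),
    protein2 = vapply(parts, `[`, "", 2L),
    called_A = called_A, called_B = called_B, status = status,
    divergence_level = lev,
    significant = status %in% c("A_specific", "B_specific") & lev != "none",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export an interaction network to TSV or GraphML
#'
#' @param net An `interaction_network`.
#' @param path Output path.
#' @param format `"tsv"` (edge list with attributes) or `"graphml"`.
#' @return `path`, invisibly. The export round-trips through
#'   [import_network()] without loss of nodes, edges or attributes.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "interaction_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    meta <- sprintf("# background=%s t=%.17g", net$background, net$t)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(meta, con)
    utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("protein1", "protein2",
                    setdiff(names(net$edges), c("protein1", "protein2")))],
      directed = FALSE,
      vertices = data.frame(name = net$nodes$protein,
                            species = ifelse(is.na(net$nodes$species), "",
                                             net$nodes$species)))
    igraph::graph_attr(g, "background") <- net$background
    igraph::graph_attr(g, "t") <- net$t
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import an interaction network written by [export_network()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"graphml"`.
#' @return An `interaction_network`.
#' @export
import_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    meta <- readLines(path, n = 1L)
    kv <- regmatches(meta, regexec("background=(\\S+) t=(\\S+)", meta))[[1L]]
    edges <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
    bg <- kv[2L]; t <- as.numeric(kv[3L])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    edges <- igraph::as_data_frame(g, what = "edges")
    names(edges)[1:2] <- c("protein1", "protein2")
    bg <- igraph::graph_attr(g, "background")
    t <- igraph::graph_attr(g, "t")
    # GraphML has no missing-value notion: undo igraph's NA encodings
    for (cn in names(edges)) {
      if (is.character(edges[[cn]])) edges[[cn]][edges[[cn]] == "NA"] <- NA
      if (is.numeric(edges[[cn]])) edges[[cn]][is.nan(edges[[cn]])] <- NA
    }
  }
  if (identical(bg, "NA")) bg <- NA_character_
  edges$background <- rep(bg, nrow(edges))
  keep <- c("protein1", "protein2", "background", "si_fwd", "si_rev",
            "si_max", "n_orient", "called", "support")
  edges <- edges[, intersect(keep, names(edges))]
  edges$called <- as.logical(edges$called)
  attr(edges, "t") <- t
  class(edges) <- c("interaction_calls", "data.frame")
  interaction_network(edges)
}
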