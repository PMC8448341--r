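#' Build a maturation reference from scored, labeled cells
#'
#' Aggregates QC-passed entropy scores into ordered stage summaries: one row
#' per (species, timepoint), carrying the median and quartiles of the score,
#' the number of cells, and the number of contributing studies. Stages with
#' no cells are dropped with a warning.
#'
#' @param scores `DataFrame` from [entropyScores()] (needs `cell_id`,
#'   `score`).
#' @param metadata Per-cell metadata with `cell_id`, `study_id`,
#'   `timepoint_label`, `timepoint_rank`, optionally `species`.
#' @return A [MaturationReference-class].
#' @export
buildReference <- function(scores, metadata) {
  md <- as.data.frame(metadata)
  idx <- match(scores$cell_id, md$cell_id)
  if (anyNA(idx))
    .stopf("scored cell '%s' absent from metadata",
           scores$cell_id[which(is.na(idx))[1]])
  sp <- if ("species" %in% colnames(md)) md$species[idx] else "unspecified"
  df <- data.frame(score = scores$score,
                   species = sp,
                   stage = md$timepoint_label[idx],
                   rank = md$timepoint_rank[idx],
                   study = md$study_id[idx],
                   stringsAsFactors = FALSE)
  key <- paste(df$species, df$stage, sep = "\r")
  agg <- lapply(split(df, key), function(d) {
    q <- quantile(d$score, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(stage_label = d$stage[1], timepoint_rank = d$rank[1],
               species = d$species[1], median_score = q[2],
               q25 = q[1], q75 = q[3], n_cells = nrow(d),
               n_studies = length(unique(d$study)),
               stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, agg)
  st <- st[order(st$species, st$timepoint_rank), , drop = FALSE]
  rownames(st) <- NULL
  k <- unique(scores$k_requested)
  lb <- unique(scores$log_base)
  methods::new("MaturationReference",
               stages = S4Vectors::DataFrame(st),
               scoreParams = list(k = if (length(k) == 1) k else NA,
                                  log_base = if (length(lb) == 1) lb else NA),
               version = "1")
}

#' Place query cells on a maturation reference
#'
#' Formalizes "this in vitro population scores like stage X in vivo": for
#' each query group, the group's median entropy score is located between the
#' bracketing reference-stage medians and expressed as a linear
#' interpolation coordinate (0 = at the earlier/higher-entropy stage's
#' median, 1 = at the later stage's). Queries outside the reference range
#' are clamped to the end stage and flagged `"beyond-reference"`; queries
#' landing exactly on a stage median get coordinate 0 at that stage.
#'
#' Placement is on group medians by default (matching how dataset-level
#' correspondences are reported); `per_cell = TRUE` instead places every
#' cell individually. Cross-species placement is allowed — the result always
#' carries the reference species.
#'
#' @param query `DataFrame` from [entropyScores()] for the query cells.
#' @param reference A [MaturationReference-class] with at least 2 stages.
#'   For a multi-species reference, `species` selects the trajectory.
#' @param groups Optional factor/character vector (one per query row)
#'   defining query groups; default places all query cells as one group.
#' @param species Reference species to stage against (defaults to the only
#'   species present).
#' @param per_cell Place each cell separately instead of group medians.
#' @return `DataFrame`: one row per group (or cell): `group`,
#'   `median_score`, `n_cells`, `stage_below` (earlier stage, higher
#'   entropy), `stage_above`, `interp` in `[0, 1]`, `stage_call` (nearest
#'   stage), `flag` (`""` or `"beyond-reference"`), `reference_species`.
#' @export
stageCells <- function(query, reference, groups = NULL, species = NULL,
                       per_cell = FALSE) {
  stopifnot(is(reference, "MaturationReference"))
  if (!nrow(query)) .stopf("empty query")
  st <- as.data.frame(reference@stages)
  if (is.null(species)) {
    if (length(unique(st$species)) > 1)
      .stopf("multi-species reference: choose a species")
    species <- st$species[1]
  }
  st <- st[st$species == species, , drop = FALSE]
  if (nrow(st) < 2) .stopf("reference needs at least 2 stages")
  st <- st[order(st$timepoint_rank), , drop = FALSE]
  if (per_cell) {
    groups <- query$cell_id
    med <- setNames(query$score, query$cell_id)
    n <- setNames(rep(1L, nrow(query)), query$cell_id)
  } else {
    if (is.null(groups)) groups <- rep("query", nrow(query))
    med <- tapply(query$score, groups, median)
    n <- tapply(query$score, groups, length)
  }
  res <- lapply(names(med), function(g) {
    .placeScore(med[[g]], st, g, as.integer(n[[g]]), species)
  })
  out <- do.call(rbind, res)
  S4Vectors::DataFrame(out, row.names = out$group)
}

## Entropy decreases with maturation: stage medians run from high (early)
## to low (late). Walk adjacent stage pairs and take the first that
## brackets the query median.
.placeScore <- function(q, st, group, n, species) {
  meds <- st$median_score
  labs <- st$stage_label
  nst <- nrow(st)
  hit <- which(abs(meds - q) < .Machine$double.eps^0.5)
  if (length(hit)) {
    i <- hit[1]
    return(data.frame(group = group, median_score = q, n_cells = n,
                      stage_below = labs[i],
                      stage_above = if (i < nst) labs[i + 1] else labs[i],
                      interp = 0, stage_call = labs[i], flag = "",
                      reference_species = species,
                      stringsAsFactors = FALSE))
  }
  if (q > max(meds)) {
    i <- which.max(meds)
    return(data.frame(group = group, median_score = q, n_cells = n,
                      stage_below = labs[i], stage_above = labs[i],
                      interp = 0, stage_call = labs[i],
                      flag = "beyond-reference",
                      reference_species = species, stringsAsFactors = FALSE))
  }
  if (q < min(meds)) {
    i <- which.min(meds)
    return(data.frame(group = group, median_score = q, n_cells = n,
                      stage_below = labs[i], stage_above = labs[i],
                      interp = 0, stage_call = labs[i],
                      flag = "beyond-reference",
                      reference_species = species, stringsAsFactors = FALSE))
  }
  for (i in seq_len(nst - 1L)) {
    lo <- meds[i]; hi <- meds[i + 1L]
    if ((q <= lo && q >= hi) || (q >= lo && q <= hi)) {
      t <- (lo - q) / (lo - hi)
      return(data.frame(group = group, median_score = q, n_cells = n,
                        stage_below = labs[i], stage_above = labs[i + 1L],
                        interp = t,
                        stage_call = if (t <= 0.5) labs[i] else labs[i + 1L],
                        flag = "", reference_species = species,
                        stringsAsFactors = FALSE))
    }
  }
  ## between-range score falling in a non-monotone gap: nearest stage
  i <- which.min(abs(meds - q))
  data.frame(group = group, median_score = q, n_cells = n,
             stage_below = labs[i], stage_above = labs[i],
             interp = 0, stage_call = labs[i], flag = "non-monotone-gap",
             reference_species = species, stringsAsFactors = FALSE)
}

#' Serialize / read a maturation reference
#'
#' CSV with a versioned comment header recording the scoring parameters, so
#' a reference can be shared without the cells it was built from.
#'
#' @param reference A [MaturationReference-class].
#' @param path Output (input) CSV path.
#' @return `writeReference()`: `path` invisibly; `readReference()`: a
#'   [MaturationReference-class].
#' @export
writeReference <- function(reference, path) {
  stopifnot(is(reference, "MaturationReference"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# entropyScore maturation reference v%s k=%s log_base=%s",
                     reference@version,
                     format(reference@scoreParams$k %||% NA),
                     format(reference@scoreParams$log_base %||% NA)), con)
  write.csv(as.data.frame(reference@stages), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReference
#' @export
readReference <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# entropyScore maturation reference v", lines[1]))
    .stopf("'%s' is not a serialized maturation reference", path)
  hdr <- lines[1]
  ver <- sub("^# entropyScore maturation reference v(\\S+).*$", "\\1", hdr)
  getnum <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    if (!length(m)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0(key, "="), "", m)))
  }
  st <- read.csv(text = lines[-1], stringsAsFactors = FALSE)
  methods::new("MaturationReference", stages = S4Vectors::DataFrame(st),
               scoreParams = list(k = getnum("k"), log_base = getnum("log_base")),
               version = ver)
}
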