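#' Structural annotation for the 24 UPLC IgG glycan peaks
#'
#' Loads the shipped per-peak annotation: core fucosylation (F), bisecting
#' GlcNAc (B), galactose count (G0/G1/G2) and sialic acid count (S0/S1/S2).
#' Peaks with `sial == 0` are the neutral glycans. The `source` column flags
#' which assignments are printed anchors (GP4 = FA2, GP8/GP9 = FA2G1,
#' GP14 = FA2G2, GP21 = A2G2S2) and which are conventional fills for peaks
#' whose exact composition is not published; edit the file to override.
#'
#' @param path optional path to an annotation TSV with columns peak,
#'   structure, fucosylated, bisecting, gal, sial
#' @return data.frame of 24 rows
#' @export
default_peak_annotation <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "glycan_peak_annotation.tsv",
                        package = "twinglyco", mustWork = TRUE)
  ann <- read_tsv(path)
  need <- c("peak", "fucosylated", "bisecting", "gal", "sial")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ann$peak)) stop("duplicate peak ids", call. = FALSE)
  ann
}

#' The shipped derived-trait definition table
#'
#' One row per trait: a numerator and denominator, each a `+`-separated list
#' of group tokens (see [parse_group_token()]), and a reporting scale
#' (`ratio`, `percent`, `permille`). The default file defines the standard 76
#' traits: 22 directly measured peak percentages, 17 sialylation ratios, 14
#' neutral peak percentages and 23 derived neutral-glycan traits.
#'
#' @param path optional path to a definitions TSV
#' @param annotation peak annotation used to validate every token
#' @return data.frame with class `trait_definitions`
#' @export
default_trait_definitions <- function(path = NULL,
                                      annotation = default_peak_annotation()) {
  if (is.null(path))
    path <- system.file("extdata", "glycan_trait_definitions.tsv",
                        package = "twinglyco", mustWork = TRUE)
  defs <- read_tsv(path)
  validate_trait_definitions(defs, annotation)
}

validate_trait_definitions <- function(defs, annotation) {
  need <- c("name", "numerator", "denominator", "scale")
  miss <- setdiff(need, names(defs))
  if (length(miss))
    stop("definitions are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(defs$name))
    stop("duplicate trait names: ",
         paste(unique(defs$name[duplicated(defs$name)]), collapse = ", "),
         call. = FALSE)
  bad_scale <- setdiff(defs$scale, c("ratio", "percent", "permille"))
  if (length(bad_scale))
    stop("unknown scale: ", paste(bad_scale, collapse = ", "), call. = FALSE)
  # every token must select at least one peak: definition error at load time
  for (i in seq_len(nrow(defs))) {
    for (expr in c(defs$numerator[i], defs$denominator[i])) {
      if (expr == "1") next
      for (tok in strsplit(expr, "+", fixed = TRUE)[[1]]) {
        sel <- match_peaks(annotation, parse_group_token(tok))
        if (!any(sel))
          stop("definition '", defs$name[i], "': token '", trimws(tok),
               "' selects no peaks", call. = FALSE)
      }
    }
  }
  class(defs) <- c("trait_definitions", "data.frame")
  defs
}

#' Parse a glycan group token into feature predicates
#'
#' The trait nomenclature is systematic, so groups are parsed from a small
#' grammar instead of being enumerated by hand:
#' \itemize{
#'   \item `GPk` / `GPkn` — a single peak, raw or neutral-normalized basis.
#'   \item `F` — core-fucosylated without bisecting GlcNAc; `Ftotal` lifts the
#'     bisecting restriction; `FB` — fucosylated with bisecting; a leading `B`
#'     without `F` — bisecting without core fucose.
#'   \item `G0`/`G1`/`G2` — exact galactose count; bare `G` — at least one.
#'   \item `S1`/`S2` — exact sialic acid count; bare `S` or `Stotal` — at
#'     least one. A token without any S element refers to neutral
#'     (asialylated) structures.
#'   \item trailing `n` — evaluate on the neutral-normalized basis (percent
#'     of all neutral glycans); a trailing `total` after `n` lifts the
#'     bisecting restriction (e.g. `Fn total`).
#'   \item a bare `F`/`FB`/`B` token with no G and no S element (as in
#'     `FGS/(F+FG+FGS)`) denotes the agalactosylated neutral group.
#' }
#'
#' @param token character scalar, e.g. `"FBG2S1"`, `"Fn total"`, `"GP8n"`
#' @return list of constraints plus the evaluation basis
#' @export
parse_group_token <- function(token) {
  s <- gsub("[[:space:]‰]", "", token)
  if (s == "") stop("empty group token", call. = FALSE)
  if (grepl("^GP[0-9]+n?$", s)) {
    return(list(peak = sub("n$", "", s), neutral_basis = grepl("n$", s)))
  }
  # "Fn total" / "FG0n total" arrive as "Fntotal"/"FG0ntotal": the trailing
  # total lifts the bisecting restriction, same as Ftotal
  lift_bisecting <- grepl("ntotal$", s)
  if (lift_bisecting) s <- sub("total$", "", s)
  rx <- "^(Ftotal|F)?(B)?(G[0-2]?)?(Stotal|S[1-2]?)?(n)?$"
  if (!grepl(rx, s)) stop("cannot parse group token: '", token, "'",
                          call. = FALSE)
  parts <- regmatches(s, regexec(rx, s))[[1]][-1]
  names(parts) <- c("F", "B", "G", "S", "n")
  if (!nzchar(paste(parts, collapse = "")))
    stop("cannot parse group token: '", token, "'", call. = FALSE)
  pred <- list(fuc = NA, bis = NA, gal_min = 0L, gal_max = 2L,
               sial_min = 0L, sial_max = 2L,
               neutral_basis = nzchar(parts[["n"]]))
  if (nzchar(parts[["F"]])) {
    pred$fuc <- TRUE
    if (parts[["F"]] == "F") pred$bis <- FALSE   # Ftotal: either
  } else if (nzchar(parts[["B"]])) {
    pred$fuc <- FALSE
  }
  if (nzchar(parts[["B"]])) pred$bis <- TRUE
  g <- parts[["G"]]
  if (g == "G") {
    pred$gal_min <- 1L
  } else if (nzchar(g)) {
    pred$gal_min <- pred$gal_max <- as.integer(substring(g, 2))
  }
  sx <- parts[["S"]]
  if (sx %in% c("S", "Stotal")) {
    pred$sial_min <- 1L
  } else if (nzchar(sx)) {
    pred$sial_min <- pred$sial_max <- as.integer(substring(sx, 2))
  } else {
    pred$sial_min <- pred$sial_max <- 0L
    # bare F / FB / B in a raw-basis expression means the agalactosylated
    # group; with the n suffix the token spans all galactose counts
    if (!pred$neutral_basis && g == "" && (nzchar(parts[["F"]]) ||
                                           nzchar(parts[["B"]])))
      pred$gal_max <- 0L
  }
  if (lift_bisecting && !nzchar(parts[["B"]])) pred$bis <- NA
  pred
}

#' Select the peaks matching a parsed group predicate
#'
#' @param annotation peak annotation table
#' @param pred result of [parse_group_token()]
#' @return logical vector over annotation rows
#' @export
match_peaks <- function(annotation, pred) {
  if (!is.null(pred$peak)) return(annotation$peak == pred$peak)
  ok <- rep(TRUE, nrow(annotation))
  if (!is.na(pred$fuc)) ok <- ok & (annotation$fucosylated == 1) == pred$fuc
  if (!is.na(pred$bis)) ok <- ok & (annotation$bisecting == 1) == pred$bis
  ok & annotation$gal >= pred$gal_min & annotation$gal <= pred$gal_max &
    annotation$sial >= pred$sial_min & annotation$sial <= pred$sial_max
}

#' Neutral-normalized peak percentages
#'
#' For every neutral (asialylated) peak k, GPkn = 100 * peak_k / sum over all
#' neutral peaks, so the GPn columns sum to 100 per sample. Samples whose
#' neutral sum is not positive get NA across all GPn columns and are reported
#' in the `errors` attribute.
#'
#' @param peak_matrix samples x 24 matrix of raw peak percentages
#' @param annotation peak annotation covering all columns
#' @return matrix of GPkn columns with an `errors` attribute (sample ids)
#' @export
neutral_percentages <- function(peak_matrix,
                                annotation = default_peak_annotation()) {
  missing_peaks <- setdiff(colnames(peak_matrix), annotation$peak)
  if (length(missing_peaks))
    stop("annotation does not cover peaks: ",
         paste(missing_peaks, collapse = ", "), call. = FALSE)
  neutral <- annotation$peak[annotation$sial == 0]
  neutral <- intersect(colnames(peak_matrix), neutral)
  if (!length(neutral)) {
    out <- matrix(numeric(0), nrow(peak_matrix), 0)
    rownames(out) <- rownames(peak_matrix)
    attr(out, "errors") <- character(0)
    return(out)
  }
  sub <- peak_matrix[, neutral, drop = FALSE]
  tot <- rowSums(sub)
  bad <- !is.finite(tot) | tot <= 0
  tot[bad] <- NA_real_
  out <- 100 * sub / tot
  colnames(out) <- paste0(neutral, "n")
  errs <- rownames(peak_matrix)[bad]
  if (is.null(errs)) errs <- which(bad)
  attr(out, "errors") <- errs
  out
}

#' Sum the peaks selected by a group token
#'
#' @param peak_matrix samples x peaks matrix of raw percentages
#' @param token group token, e.g. `"FBGS"` or `"G0n"`
#' @param annotation peak annotation
#' @param neutral optional precomputed [neutral_percentages()] matrix
#' @return numeric vector, one value per sample
#' @export
group_sum <- function(peak_matrix, token,
                      annotation = default_peak_annotation(),
                      neutral = NULL) {
  pred <- parse_group_token(token)
  sel <- match_peaks(annotation, pred)
  if (!any(sel))
    stop("token '", token, "' selects no peaks", call. = FALSE)
  if (isTRUE(pred$neutral_basis)) {
    if (is.null(neutral)) neutral <- neutral_percentages(peak_matrix, annotation)
    cols <- paste0(annotation$peak[sel], "n")
    cols <- intersect(cols, colnames(neutral))
    if (!length(cols))
      stop("token '", token, "' selects no neutral peaks", call. = FALSE)
    rowSums(neutral[, cols, drop = FALSE])
  } else {
    cols <- intersect(annotation$peak[sel], colnames(peak_matrix))
    rowSums(peak_matrix[, cols, drop = FALSE])
  }
}

group_expr_sum <- function(peak_matrix, expr, annotation, neutral) {
  if (expr == "1") return(rep(1, nrow(peak_matrix)))
  toks <- strsplit(expr, "+", fixed = TRUE)[[1]]
  vals <- lapply(toks, group_sum, peak_matrix = peak_matrix,
                 annotation = annotation, neutral = neutral)
  Reduce(`+`, vals)
}

#' Evaluate one derived-trait definition
#'
#' Numerator over denominator on the requested scale (`percent` multiplies by
#' 100, `permille` by 1000). A zero denominator yields NA for that sample
#' with a warning, not an error, so cohort stages can drop the record.
#'
#' @param definition one-row slice of a definitions table
#' @param peak_matrix samples x peaks matrix
#' @param annotation peak annotation
#' @param neutral optional precomputed neutral-basis matrix
#' @return numeric vector, one value per sample
#' @export
evaluate_trait <- function(definition, peak_matrix,
                           annotation = default_peak_annotation(),
                           neutral = NULL) {
  num <- group_expr_sum(peak_matrix, definition$numerator, annotation, neutral)
  den <- group_expr_sum(peak_matrix, definition$denominator, annotation, neutral)
  zero <- is.finite(den) & den == 0
  if (any(zero)) {
    warning("trait '", definition$name, "': zero denominator for ",
            sum(zero), " sample(s); values set to NA", call. = FALSE)
    den[zero] <- NA_real_
  }
  mult <- switch(definition$scale, ratio = 1, percent = 100, permille = 1000)
  mult * num / den
}

#' Compute the full derived-trait matrix from a peak table
#'
#' With the shipped definitions this yields the standard 76 trait columns;
#' with an empty definitions table it returns the raw peak columns unchanged.
#'
#' @param peak_matrix samples x peaks matrix (or data.frame with a sample_id
#'   column, as written by [write_cohort()])
#' @param annotation peak annotation
#' @param definitions a validated definitions table
#' @return samples x traits matrix
#' @export
compute_all_traits <- function(peak_matrix,
                               annotation = default_peak_annotation(),
                               definitions = default_trait_definitions(
                                 annotation = annotation)) {
  if (is.data.frame(peak_matrix) && "sample_id" %in% names(peak_matrix))
    peak_matrix <- table_to_matrix(peak_matrix)
  if (nrow(definitions) == 0L) return(peak_matrix)
  definitions <- validate_trait_definitions(as.data.frame(definitions),
                                            annotation)
  neutral <- neutral_percentages(peak_matrix, annotation)
  out <- matrix(NA_real_, nrow(peak_matrix), nrow(definitions),
                dimnames = list(rownames(peak_matrix), definitions$name))
  for (i in seq_len(nrow(definitions))) {
    out[, i] <- evaluate_trait(definitions[i, ], peak_matrix, annotation,
                               neutral)
  }
  message("computed ", ncol(out), " glycan traits for ", nrow(out),
          " samples")
  out
}
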