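# Diagnostic electron-impact ions the rule cascade relies on. The m/z 129 /
# 102 base peaks separate fructitol from glucitol backbones; 189/190 flag O6
# vs O1 acetylation on fructose; 205 and 233 flag the glucose C2-C3 cleavage
# and the extra C6 acetylation of an internal glucose; the 161/162 pair marks
# the epimer mixture of the convolved (2->6/1) peak.
DIAGNOSTIC_IONS <- c(102L, 129L, 161L, 162L, 189L, 190L, 205L, 233L)

PMAA_CLASSES <- c(LINKAGE_CLASSES, "b261_fruf")

#' Construct a PMAA mass spectrum
#'
#' A spectrum is a list of (m/z, relative intensity) pairs with the base peak
#' at 100. Intensities are rescaled so the most intense peak is exactly 100.
#'
#' @param mz positive integer m/z values (unit mass).
#' @param intensity intensities, any positive scale; rescaled to percent of
#'   base peak.
#' @param name optional spectrum name.
#' @param metadata optional named list carried along (retention time, source
#'   peak number, ...).
#' @return object of class `pmaa_spectrum` with elements `mz`, `intensity`,
#'   `name`, `metadata`.
#' @export
pmaa_spectrum <- function(mz, intensity, name = NULL, metadata = list()) {
  if (length(mz) == 0) stop("a PMAA spectrum needs at least one peak")
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(mz <= 0) || any(abs(mz - round(mz)) > 1e-9)) {
    stop("m/z values must be positive integers (unit-mass spectra)")
  }
  if (any(intensity <= 0)) stop("intensities must be positive")
  o <- order(mz)
  mz <- as.integer(round(mz[o]))
  intensity <- intensity[o]
  if (anyDuplicated(mz)) stop("duplicate m/z in spectrum")
  structure(list(mz = mz,
                 intensity = 100 * intensity / max(intensity),
                 name = name, metadata = metadata),
            class = "pmaa_spectrum")
}

#' @export
print.pmaa_spectrum <- function(x, ...) {
  cat("<pmaa_spectrum>", x$name %||% "(unnamed)", "-", length(x$mz), "peaks\n")
  top <- order(x$intensity, decreasing = TRUE)[seq_len(min(5, length(x$mz)))]
  cat(" ", paste(sprintf("%d(%.1f)", x$mz[top], x$intensity[top]),
                 collapse = ", "), "\n")
  invisible(x)
}

#' Cosine similarity of two PMAA spectra
#'
#' Intensities are matched on exact integer m/z (unit-mass printed spectra)
#' and compared by the normalized dot product. Identical spectra score 1,
#' spectra with no shared ions score 0; the score is symmetric and invariant
#' to uniform intensity rescaling.
#'
#' @param a,b [pmaa_spectrum()] objects.
#' @return similarity in `[0, 1]`.
#' @export
cosine_score <- function(a, b) {
  stopifnot(inherits(a, "pmaa_spectrum"), inherits(b, "pmaa_spectrum"))
  if (!length(a$mz) || !length(b$mz)) stop("cannot score an empty spectrum")
  grid <- union(a$mz, b$mz)
  va <- vb <- numeric(length(grid))
  va[match(a$mz, grid)] <- a$intensity
  vb[match(b$mz, grid)] <- b$intensity
  as.numeric(crossprod(va, vb) / sqrt(crossprod(va) * crossprod(vb)))
}

#' The packaged PMAA reference library
#'
#' Eight reference entries (retention time, derivative name, linkage class,
#' fragmentation pattern) covering the six linkage classes plus the convolved
#' `(2->6/1)-Fruf` glucitol-epimer peak, shipped as an MSP fixture.
#'
#' @return list of entries, each with `peak_number`, `retention_time`,
#'   `derivative_name`, `linkage_class` and `spectrum`.
#' @export
pmaa_reference_library <- function() {
  path <- system.file("extdata", "pmaa_reference.msp", package = "agavin")
  spectra <- read_msp(path)
  lapply(spectra, function(s) {
    list(peak_number = as.integer(s$metadata$Peak),
         retention_time = as.numeric(s$metadata$RT),
         derivative_name = s$metadata$Derivative,
         linkage_class = s$metadata$LinkageClass,
         spectrum = s)
  })
}

#' Classify a PMAA spectrum into a linkage class
#'
#' Applies the diagnostic-ion rule cascade: a base peak at m/z 102 indicates a
#' glucitol backbone (m/z 233 present -> internal glucose, else m/z 205 ->
#' terminal glucose); a base peak at m/z 129 indicates a fructose backbone,
#' split by the O6/O1 acetylation markers m/z 189 and 190 (neither ->
#' terminal, 189 only -> 2->6, 190 only -> 2->1, both with the 161/162 epimer
#' pair -> convolved 2->6/1, both without it -> the 1,6-di branch residue).
#' When no rule fires the spectrum falls back to its best cosine match in the
#' reference library; matches below `fallback_threshold` are reported as
#' `"unclassified"` rather than raising an error.
#'
#' @param s a [pmaa_spectrum()].
#' @param library reference library (default [pmaa_reference_library()]).
#' @param fallback_threshold minimum cosine score accepted from the fallback
#'   (default 0.5).
#' @return list with `linkage_class`, `evidence` (character vector of fired
#'   rules) and `cosine_best` (named best library score).
#' @export
classify_spectrum <- function(s, library = pmaa_reference_library(),
                              fallback_threshold = 0.5) {
  stopifnot(inherits(s, "pmaa_spectrum"))
  has <- function(m) m %in% s$mz
  base <- s$mz[which.max(s$intensity)]
  evidence <- character()
  cls <- NULL
  if (base == 102L) {
    evidence <- "base peak m/z 102: glucitol backbone"
    if (has(233L)) {
      cls <- "i_glcp"
      evidence <- c(evidence, "m/z 233: extra acetylation at C6")
    } else if (has(205L)) {
      cls <- "t_glcp"
      evidence <- c(evidence, "m/z 205: C2-C3 cleavage next to methoxylated carbons")
    }
  } else if (base == 129L) {
    evidence <- "base peak m/z 129: fructose backbone"
    m189 <- has(189L); m190 <- has(190L)
    if (!m189 && !m190) {
      cls <- "t_fruf"
      evidence <- c(evidence, "no m/z 189/190: unsubstituted C1 and C6")
    } else if (m189 && !m190) {
      cls <- "b26_fruf"
      evidence <- c(evidence, "m/z 189 without 190: acetylation at O6")
    } else if (m190 && !m189) {
      cls <- "b21_fruf"
      evidence <- c(evidence, "m/z 190 without 189: acetylation at O1")
    } else if (has(161L) && has(162L)) {
      cls <- "b261_fruf"
      evidence <- c(evidence,
                    "m/z 189 and 190 with 161/162 epimer pair: convolved 2->6/1")
    } else {
      cls <- "di_fruf"
      evidence <- c(evidence,
                    "m/z 189 and 190 without 161/162: substitution at both O1 and O6")
    }
  }
  scores <- vapply(library, function(e) cosine_score(s, e$spectrum), numeric(1))
  names(scores) <- vapply(library, function(e) e$linkage_class, character(1))
  best <- which.max(scores)
  if (is.null(cls)) {
    if (scores[best] >= fallback_threshold) {
      cls <- names(scores)[best]
      evidence <- c(evidence, sprintf(
        "cosine fallback: best match %s (score %.3f)", cls, scores[best]))
    } else {
      cls <- "unclassified"
      evidence <- c(evidence, sprintf(
        "no rule fired and best cosine %.3f < %.2f", scores[best],
        fallback_threshold))
    }
  }
  list(linkage_class = cls, evidence = evidence,
       cosine_best = scores[best])
}

#' Convert per-peak GC areas to class molar percentages
#'
#' Peak areas are pooled by linkage class assuming equal molar response
#' across PMAA derivatives: the two terminal-fructose epimer peaks (1, 2) are
#' summed, and the convolved glucitol peak 6 is split between the 2->1 and
#' 2->6 classes in proportion to their resolved mannitol epimer peaks 5 and 4
#' (50/50 when both are zero). The result is normalized to percentages
#' summing to 100.
#'
#' @param areas named numeric vector of GC peak areas; names are the peak
#'   numbers `"1"`..`"8"`. Missing peaks count as zero area.
#' @return named numeric vector over the six linkage classes summing to 100.
#' @export
quantify_molar_percent <- function(areas) {
  if (is.null(names(areas))) {
    stop("areas must be named by peak number (\"1\"..\"8\")")
  }
  bad <- setdiff(names(areas), as.character(1:8))
  if (length(bad)) stop("unknown peak number(s): ", paste(bad, collapse = ", "))
  if (any(areas < 0)) stop("peak areas must be non-negative")
  a <- stats::setNames(numeric(8), as.character(1:8))
  a[names(areas)] <- areas
  if (sum(a) == 0) stop("all peak areas are zero")
  split46 <- if (a[["4"]] + a[["5"]] > 0) {
    a[["4"]] / (a[["4"]] + a[["5"]])
  } else 0.5
  cls <- c(
    t_fruf   = a[["1"]] + a[["2"]],
    b21_fruf = a[["5"]] + a[["6"]] * (1 - split46),
    b26_fruf = a[["4"]] + a[["6"]] * split46,
    di_fruf  = a[["8"]],
    t_glcp   = a[["3"]],
    i_glcp   = a[["7"]]
  )
  as_census(100 * cls / sum(cls))
}

#' Classify a batch of spectra into a report table
#'
#' @param spectra list of [pmaa_spectrum()] objects.
#' @param library reference library (default [pmaa_reference_library()]).
#' @return data.frame with columns `peak`, `rt_min`, `assigned_class`,
#'   `rule_evidence`, `cosine_best`.
#' @export
classification_report <- function(spectra, library = pmaa_reference_library()) {
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    cl <- classify_spectrum(s, library)
    data.frame(
      peak = s$metadata$Peak %||% i,
      rt_min = as.numeric(s$metadata$RT %||% NA),
      assigned_class = cl$linkage_class,
      rule_evidence = paste(cl$evidence, collapse = "; "),
      cosine_best = as.numeric(cl$cosine_best),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
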