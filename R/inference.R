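RATIO_CLASSES <- c("t_fruf", "b21_fruf", "b26_fruf", "di_fruf", "glcp")

#' Glucose-normalized molar ratios
#'
#' Because a fructan carries at most one glucose, dividing each linkage
#' class's molar percentage by the summed terminal + internal glucose
#' percentage expresses every class as residues per molecule. The glucose
#' ratio is 1 by construction; ratios are invariant to uniform rescaling of
#' the percentages.
#'
#' @param percent molar percentages over the six linkage classes
#'   ([as_census()] coercible).
#' @return named numeric vector `t_fruf`, `b21_fruf`, `b26_fruf`, `di_fruf`,
#'   `glcp` (= 1), with the terminal/internal glucose percentage split kept in
#'   attribute `"glcp_split"`.
#' @export
normalize_to_glucose <- function(percent) {
  p <- as_census(percent)
  glc <- p[["t_glcp"]] + p[["i_glcp"]]
  if (glc <= 0) {
    stop("no glucose in the composition: this is an F-series mixture, ",
         "outside the glucose-normalized ratio procedure")
  }
  out <- c(p[c("t_fruf", "b21_fruf", "b26_fruf", "di_fruf")] / glc, glcp = 1)
  attr(out, "glcp_split") <- p[c("t_glcp", "i_glcp")]
  out
}

#' Core degree of polymerization of a sample
#'
#' The sum of the five glucose-normalized ratios (four fructose classes plus
#' the glucose term of 1), reported to one decimal.
#'
#' @param ratios output of [normalize_to_glucose()] or an equivalent named
#'   vector over `t_fruf`, `b21_fruf`, `b26_fruf`, `di_fruf`, `glcp`.
#' @return numeric scalar, one decimal.
#' @export
core_dp <- function(ratios) {
  r <- ratios[RATIO_CLASSES]
  if (anyNA(r)) stop("ratios must cover ", paste(RATIO_CLASSES, collapse = ", "))
  round_half_up(sum(r), 1)
}

# One ratio -> one molecule count: zero stays zero, any positive value below
# one counts as one molecule, and values >= 1 round half-up on the decimal.
assign_one <- function(v) {
  if (v < 0) stop("negative ratio: ", v)
  if (v == 0) return(0)
  if (v < 1) return(1)
  round_half_up(v)
}

#' Assign integer molecule counts to glucose-normalized ratios
#'
#' Implements the molecule-assignment rule: a ratio of exactly zero assigns no
#' residue; any value in (0, 1) assigns one; values of one or more are rounded
#' half-up on their decimal part (2.5 -> 3). The rule is applied per class and
#' is non-decreasing in each ratio.
#'
#' @param ratios named non-negative numeric vector (any subset of classes,
#'   typically from [normalize_to_glucose()]).
#' @return named integer vector of molecule counts, with attribute
#'   `"total_dp"` (their sum).
#' @examples
#' assign_molecules(c(t_fruf = 1.8, b21_fruf = 2.2, b26_fruf = 0.3,
#'                    di_fruf = 0.6, glcp = 1.0))
#' @export
assign_molecules <- function(ratios) {
  out <- vapply(as.numeric(ratios), assign_one, numeric(1))
  out <- stats::setNames(as.integer(out), names(ratios))
  attr(out, "total_dp") <- sum(out)
  out
}

sd_population <- function(x) {
  n <- length(x)
  stats::sd(x) * sqrt((n - 1) / n)
}

#' Cross-sample summary of ratios and assigned counts
#'
#' Means per class, per core-DP and per assigned DP, with both standard
#' deviation conventions reported side by side: `sd_sample` uses the usual
#' n - 1 denominator (the default in reports), `sd_population` uses n.
#'
#' @param ratio_table data.frame of per-sample ratios (columns `t_fruf`,
#'   `b21_fruf`, `b26_fruf`, `di_fruf`, `glcp`; one row per sample).
#' @param assigned_table data.frame of per-sample assigned counts, same
#'   columns.
#' @return list with data.frames `ratios` and `assigned` (columns `class`,
#'   `mean`, `sd_sample`, `sd_population`) plus rows for `core_dp` and `dp`.
#' @export
summarize_linkage <- function(ratio_table, assigned_table) {
  if (nrow(ratio_table) < 2) {
    stop("need at least two samples to summarize (stdev undefined otherwise)")
  }
  smry <- function(df, extra) {
    df <- cbind(df[RATIO_CLASSES], extra)
    data.frame(
      class = names(df),
      mean = vapply(df, mean, numeric(1)),
      sd_sample = vapply(df, stats::sd, numeric(1)),
      sd_population = vapply(df, sd_population, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  cd <- apply(ratio_table[RATIO_CLASSES], 1, function(r) core_dp(r))
  dps <- rowSums(assigned_table[RATIO_CLASSES])
  list(ratios = smry(ratio_table, data.frame(core_dp = cd)),
       assigned = smry(assigned_table, data.frame(dp = dps)))
}

#' Scale assigned counts to a chromatographically determined maximum DP
#'
#' The maximum countable DP (from anion-exchange chromatography) is divided
#' by the mean assigned DP; every non-glucose count is multiplied by this
#' factor and passed back through the molecule-assignment rounding, while the
#' glucose count stays at one.
#'
#' @param assigned named counts (classes `t_fruf`, `b21_fruf`, `b26_fruf`,
#'   `di_fruf`, `glcp`).
#' @param hpaec_dp target maximum DP (e.g. 20).
#' @param mean_dp mean assigned DP used as denominator; defaults to
#'   `sum(assigned)`.
#' @return list with `counts` (scaled integer counts) and `scale_factor`.
#' @export
scale_counts <- function(assigned, hpaec_dp, mean_dp = sum(assigned)) {
  factor <- hpaec_dp / mean_dp
  if (factor < 1) {
    warning("target DP ", hpaec_dp, " is below the mean assigned DP ",
            mean_dp, "; scale factor clamped to 1")
    factor <- 1
  }
  fr <- setdiff(names(assigned), "glcp")
  out <- assigned
  out[fr] <- vapply(assigned[fr] * factor, assign_one, numeric(1))
  if ("glcp" %in% names(out)) out[["glcp"]] <- 1
  list(counts = stats::setNames(as.integer(out), names(assigned)),
       scale_factor = factor)
}

#' Branching frequency
#'
#' Number of 2->1 linkages per branch point, i.e. the ratio of the
#' `(2->1)-Fruf` to the `1,6-di-Fruf` ratio. An unbranched composition
#' (no di residues) returns `Inf`.
#'
#' @param ratios named vector containing `b21_fruf` and `di_fruf`.
#' @return positive numeric, or `Inf` for unbranched mixtures.
#' @export
branching_frequency <- function(ratios) {
  di <- ratios[["di_fruf"]]
  if (di == 0) return(Inf)
  ratios[["b21_fruf"]] / di
}

#' Neo-fructan fraction of a mixture
#'
#' Share of molecules carrying an internal glucose:
#' `i-Glcp / (t-Glcp + i-Glcp)`. A 1:1 terminal/internal glucose split (0.5)
#' indicates equal proportions of graminans and neo-fructans.
#'
#' @param percent molar percentages over the six classes ([as_census()]
#'   coercible).
#' @return numeric in `[0, 1]`.
#' @export
neo_fraction <- function(percent) {
  p <- as_census(percent)
  glc <- p[["t_glcp"]] + p[["i_glcp"]]
  if (glc <= 0) stop("no glucose in the composition; neo fraction undefined")
  p[["i_glcp"]] / glc
}

#' Propose graminan and agavin structures from assigned counts
#'
#' Assembles the canonical graminan core (terminal glucose) from the assigned
#' counts, and the agavin counterpart with an internal glucose. An internal
#' glucose consumes one extra acceptor position, so the agavin core carries
#' one additional terminal fructose on the glucose C6 and its DP is one
#' higher than the graminan's. Both cores are then extended to the
#' chromatographic maximum DP.
#'
#' @param assigned named counts over `t_fruf`, `b21_fruf`, `b26_fruf`,
#'   `di_fruf` (glucose implied as 1; a `glcp` entry is ignored).
#' @param hpaec_dp maximum countable DP to extend to (default 20).
#' @param mode extension mode passed to [extend_to_target_dp()].
#' @return list of four [fructan_structure()]s: `graminan_core`,
#'   `agavin_core`, `graminan_extended`, `agavin_extended`, plus a `report`
#'   data.frame of DP, topology and census for each.
#' @export
propose_structures <- function(assigned, hpaec_dp = 20,
                               mode = c("backbone", "proportional")) {
  mode <- match.arg(mode)
  fr <- c("t_fruf", "b21_fruf", "b26_fruf", "di_fruf")
  cnt <- vapply(fr, function(k) as.numeric(assigned[[k]] %||% 0), numeric(1))
  names(cnt) <- fr
  gram <- assemble_core(c(cnt, t_glcp = 1))
  agav_cnt <- cnt
  agav_cnt[["t_fruf"]] <- agav_cnt[["t_fruf"]] + 1  # neo cap on glucose C6
  agav <- assemble_core(c(agav_cnt, i_glcp = 1))
  gram_ext <- extend_to_target_dp(gram, max(hpaec_dp, dp(gram)), mode)
  agav_ext <- extend_to_target_dp(agav, max(hpaec_dp, dp(agav)), mode)
  all <- list(graminan_core = gram, agavin_core = agav,
              graminan_extended = gram_ext, agavin_extended = agav_ext)
  report <- do.call(rbind, lapply(names(all), function(nm) {
    s <- all[[nm]]
    cbind(data.frame(structure = nm, dp = dp(s),
                     topology = classify_topology(s),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(census(s))))
  }))
  c(all, list(report = report))
}

#' Reference linkage-ratio table for six tuberose bulb samples
#'
#' Glucose-normalized molar ratios of the four fructose linkage classes in
#' six one-year-old bulbs of the tuberose *Agave amica*, the worked example
#' dataset of this package. Read from the packaged CSV.
#'
#' @return data.frame with columns `sample`, `t_fruf`, `b21_fruf`,
#'   `b26_fruf`, `di_fruf`, `glcp`.
#' @export
amica_bulb_ratios <- function() {
  path <- system.file("extdata", "amica_bulb_ratios.csv", package = "agavin")
  df <- read_linkage_csv(path)
  df
}

#' Run the full linkage-inference procedure on a multi-sample table
#'
#' Per sample: glucose-normalized ratios (computed from percentages when the
#' input carries `_pct` columns), core DP, and assigned molecule counts.
#' Across samples: means and both standard deviation conventions, the DP
#' scale factor to the chromatographic maximum, scaled counts, branching
#' frequency, neo-fructan fraction (when the glucose split is available), and
#' proposed graminan/agavin structures.
#'
#' @param x data.frame from [read_linkage_csv()] / [amica_bulb_ratios()]:
#'   column `sample` plus either percentage columns (six classes) or ratio
#'   columns (`t_fruf`, `b21_fruf`, `b26_fruf`, `di_fruf`, `glcp`).
#' @param hpaec_dp maximum countable DP (default 20).
#' @return object of class `linkage_inference`: ratio and assigned tables,
#'   summaries, `scale_factor`, `scaled_counts`, `branching_frequency`,
#'   `neo_fraction` (or `NA` without a glucose split), and proposed
#'   structures.
#' @export
infer_linkage_table <- function(x, hpaec_dp = 20) {
  is_pct <- "t_glcp" %in% names(x)
  neo <- NA_real_
  if (is_pct) {
    rows <- lapply(seq_len(nrow(x)), function(i) {
      normalize_to_glucose(unlist(x[i, LINKAGE_CLASSES]))
    })
    ratio_table <- cbind(data.frame(sample = x$sample),
                         do.call(rbind, lapply(rows, function(r) {
                           as.data.frame(as.list(unclass(r)[RATIO_CLASSES]))
                         })))
    neo <- mean(vapply(seq_len(nrow(x)), function(i) {
      neo_fraction(unlist(x[i, LINKAGE_CLASSES]))
    }, numeric(1)))
  } else {
    ratio_table <- x[c("sample", RATIO_CLASSES)]
  }
  assigned_table <- ratio_table
  for (i in seq_len(nrow(ratio_table))) {
    assigned_table[i, RATIO_CLASSES] <-
      as.list(assign_molecules(unlist(ratio_table[i, RATIO_CLASSES])))
  }
  summaries <- summarize_linkage(ratio_table, assigned_table)
  mean_dp <- summaries$assigned$mean[summaries$assigned$class == "dp"]
  mean_assigned <- round_half_up(
    vapply(assigned_table[RATIO_CLASSES], mean, numeric(1)))
  # the scale factor uses the reported (one-decimal) average DP
  scaled <- scale_counts(mean_assigned, hpaec_dp, round_half_up(mean_dp, 1))
  mean_ratios <- vapply(ratio_table[RATIO_CLASSES], mean, numeric(1))
  structure(list(
    ratio_table = ratio_table,
    assigned_table = assigned_table,
    summary = summaries,
    hpaec_dp = hpaec_dp,
    mean_core_dp = summaries$ratios$mean[summaries$ratios$class == "core_dp"],
    mean_assigned_dp = mean_dp,
    scale_factor = scaled$scale_factor,
    scaled_counts = scaled$counts,
    branching_frequency = branching_frequency(round_half_up(mean_ratios, 1)),
    neo_fraction = neo,
    structures = propose_structures(mean_assigned, hpaec_dp)
  ), class = "linkage_inference")
}

#' @export
print.linkage_inference <- function(x, ...) {
  cat("Glycosidic-linkage inference across", nrow(x$ratio_table), "samples\n")
  cat(sprintf("  mean core-DP: %.1f   mean assigned DP: %.1f\n",
              round_half_up(x$mean_core_dp, 1),
              round_half_up(x$mean_assigned_dp, 1)))
  cat(sprintf("  scale factor to DP-%d: %.2f\n", x$hpaec_dp, x$scale_factor))
  cat(sprintf("  branching frequency: %.1f (2->1 residues per branch point)\n",
              round_half_up(x$branching_frequency, 1)))
  if (!is.na(x$neo_fraction)) {
    cat(sprintf("  neo-fructan fraction: %.2f\n", x$neo_fraction))
  }
  cat("  proposed structures:\n")
  print(x$structures$report[c("structure", "dp", "topology")],
        row.names = FALSE)
  invisible(x)
}
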