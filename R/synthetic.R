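#' Parameters of the synthetic fructan-mixture generator
#'
#' The generator grows each molecule from sucrose: the backbone is elongated
#' by 2->1 fructoses with a geometric length distribution; every backbone
#' unit that has a chain continuation may branch at C6 with probability
#' `branch_prob`, carrying a levan side chain whose extra length beyond the
#' mandatory capping fructose is geometric; with probability `neo_fraction`
#' the glucose is internal (a terminal fructose occupies its C6). Defaults
#' are tuned so the analytic mean census matches the worked-example bulb
#' composition: backbone mean 2.8 with branch probability 3/14 gives 2.2
#' expected 2->1 residues and 0.6 branch residues per molecule, levan mean
#' 0.5 gives 0.3 expected 2->6 residues, and half the molecules are
#' neo-fructans.
#'
#' @param n_structures molecules per simulated population (default 2000).
#' @param mean_backbone_len mean number of 2->1 elongation units (default
#'   2.8).
#' @param branch_prob per-unit branching probability (default 3/14).
#' @param levan_branch_len_mean mean number of 2->6 residues per branch
#'   (default 0.5; each branch additionally carries its terminal cap).
#' @param neo_fraction probability of an internal glucose (default 0.5).
#' @param seed mandatory seed for reproducibility.
#' @return object of class `mixture_params`.
#' @export
mixture_params <- function(n_structures = 2000, mean_backbone_len = 2.8,
                           branch_prob = 3 / 14, levan_branch_len_mean = 0.5,
                           neo_fraction = 0.5, seed) {
  if (missing(seed)) stop("a seed is mandatory for the generator")
  stopifnot(n_structures >= 1, mean_backbone_len >= 0,
            branch_prob >= 0, branch_prob <= 1,
            levan_branch_len_mean >= 0,
            neo_fraction >= 0, neo_fraction <= 1)
  structure(list(n_structures = n_structures,
                 mean_backbone_len = mean_backbone_len,
                 branch_prob = branch_prob,
                 levan_branch_len_mean = levan_branch_len_mean,
                 neo_fraction = neo_fraction, seed = seed),
            class = "mixture_params")
}

# Analytic per-molecule expected census of the geometric model; with B ~
# Geom(mean beta) backbone units, each branching w.p. pi with levan mean
# lambda, and neo probability nu:
#   E[2-1] = beta(1-pi), E[di] = beta*pi, E[2-6] = beta*pi*lambda,
#   E[t]   = 1 + beta*pi + nu, E[tG] = 1-nu, E[iG] = nu.

#' Analytic expected census of the mixture generator
#'
#' Closed-form per-molecule class expectations of the geometric growth
#' model, used as ground truth in recovery tests.
#'
#' @param params a [mixture_params()] object.
#' @return named numeric vector over the six linkage classes.
#' @export
expected_mixture_census <- function(params) {
  beta <- params$mean_backbone_len
  pi_b <- params$branch_prob
  lam <- params$levan_branch_len_mean
  nu <- params$neo_fraction
  as_census(c(
    t_fruf = 1 + beta * pi_b + nu,
    b21_fruf = beta * (1 - pi_b),
    b26_fruf = beta * pi_b * lam,
    di_fruf = beta * pi_b,
    t_glcp = 1 - nu,
    i_glcp = nu
  ))
}

#' Draw one fructan structure from the mixture model
#'
#' Consumes the current RNG stream (seed the stream yourself, or use the
#' table-level simulators which seed it for you). The chain tip never
#' branches, so every generated census satisfies the canonical assembly
#' feasibility conditions of [assemble_core()].
#'
#' @param params a [mixture_params()] object.
#' @return a valid [fructan_structure()].
#' @export
generate_structure <- function(params) {
  stopifnot(inherits(params, "mixture_params"))
  beta <- params$mean_backbone_len
  ids <- c("G", "S1"); sugars <- c("glucose", "fructose")
  edges <- list(data.frame(donor = "G", acceptor = "S1", position = "C2",
                           stringsAsFactors = FALSE))
  nxt <- 1L
  new_id <- function() {
    nxt <<- nxt + 1L
    sprintf("F%d", nxt)
  }
  add <- function(donor, acceptor, position) {
    edges[[length(edges) + 1L]] <<- data.frame(
      donor = donor, acceptor = acceptor, position = position,
      stringsAsFactors = FALSE)
  }
  n_units <- if (beta > 0) stats::rgeom(1, 1 / (1 + beta)) else 0L
  backbone <- "S1"
  for (i in seq_len(n_units)) {
    id <- new_id()
    ids <- c(ids, id); sugars <- c(sugars, "fructose")
    add(id, backbone[length(backbone)], "C1")
    backbone <- c(backbone, id)
  }
  # units with a C1 continuation may carry a levan branch; the tip never does
  lam <- params$levan_branch_len_mean
  for (unit in backbone[-length(backbone)]) {
    if (stats::runif(1) < params$branch_prob) {
      extra <- if (lam > 0) stats::rgeom(1, 1 / (1 + lam)) else 0L
      anchor <- unit
      for (j in seq_len(extra + 1L)) {
        id <- new_id()
        ids <- c(ids, id); sugars <- c(sugars, "fructose")
        add(id, anchor, "C6")
        anchor <- id
      }
    }
  }
  if (stats::runif(1) < params$neo_fraction) {
    id <- new_id()
    ids <- c(ids, id); sugars <- c(sugars, "fructose")
    add(id, "G", "C6")
  }
  fructan_structure(
    residues = data.frame(id = ids, sugar = sugars, stringsAsFactors = FALSE),
    edges = do.call(rbind, edges)
  )
}

# multiplicative lognormal noise with unit mean and the given CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a multi-sample PMAA molar-percentage table
#'
#' Draws one population of structures, aggregates their censuses into a
#' population molar-percentage composition, and emulates biological/
#' analytical replicate scatter by perturbing each sample with multiplicative
#' lognormal noise of the given coefficient of variation, renormalized to
#' 100%.
#'
#' @param params a [mixture_params()] object.
#' @param n_samples number of samples (default 6).
#' @param noise_cv per-class coefficient of variation (default 0.05).
#' @param seed seed; defaults to `params$seed`.
#' @return data.frame `sample` plus the six linkage-class percentage columns;
#'   the noise-free population percentages are kept in attribute
#'   `"population_percent"`.
#' @export
simulate_pmaa_table <- function(params, n_samples = 6, noise_cv = 0.05,
                                seed = params$seed) {
  stopifnot(inherits(params, "mixture_params"), n_samples >= 1, noise_cv >= 0)
  with_seed(seed, {
    total <- as_census(stats::setNames(numeric(6), LINKAGE_CLASSES))
    for (i in seq_len(params$n_structures)) {
      total <- total + census(generate_structure(params))
    }
    pop_pct <- 100 * total / sum(total)
    rows <- lapply(seq_len(n_samples), function(i) {
      v <- pop_pct * lognormal_noise(length(pop_pct), noise_cv)
      100 * v / sum(v)
    })
    out <- cbind(data.frame(sample = sprintf("S%d", seq_len(n_samples))),
                 do.call(rbind, lapply(rows, function(r) {
                   as.data.frame(as.list(r))
                 })))
    attr(out, "population_percent") <- pop_pct
    out
  })
}

#' Simulate a PMAA spectrum of a known linkage class
#'
#' Takes the reference spectrum of the class, jitters intensities with
#' truncated Gaussian noise, renormalizes the base peak to 100 and never
#' drops the diagnostic ions the rule cascade relies on (non-diagnostic peaks
#' whose jittered intensity falls to zero are removed).
#'
#' @param linkage_class one of the reference library classes (`t_fruf`,
#'   `b21_fruf`, `b26_fruf`, `di_fruf`, `t_glcp`, `i_glcp`, `b261_fruf`).
#' @param jitter_sd Gaussian intensity jitter, percent of base peak
#'   (default 0: exact reference spectrum).
#' @param seed optional seed.
#' @return a [pmaa_spectrum()].
#' @export
simulate_spectrum <- function(linkage_class, jitter_sd = 0, seed = NULL) {
  lib <- pmaa_reference_library()
  hit <- Filter(function(e) e$linkage_class == linkage_class, lib)
  if (!length(hit)) {
    stop("unknown linkage class '", linkage_class, "'; library covers: ",
         paste(unique(vapply(lib, `[[`, character(1), "linkage_class")),
               collapse = ", "))
  }
  ref <- hit[[1]]$spectrum
  with_seed(seed, {
    intensity <- ref$intensity + stats::rnorm(length(ref$mz), 0, jitter_sd)
    diagnostic <- ref$mz %in% DIAGNOSTIC_IONS
    intensity[diagnostic] <- pmax(intensity[diagnostic], 0.1)
    keep <- intensity > 0
    pmaa_spectrum(ref$mz[keep], intensity[keep],
                  name = paste0("simulated ", linkage_class),
                  metadata = list(source_class = linkage_class,
                                  jitter_sd = jitter_sd))
  })
}

#' Parameters of the HPTLC band-table simulator
#'
#' Emulates a two-class (young vs old) thin-layer-chromatography band table:
#' a shared baseline intensity profile over the Rf grid, class effects
#' applied multiplicatively to the old class, and lognormal noise. The
#' default grid carries the four anchor bands (fructose 0.57, sucrose 0.51,
#' the DP-3 kestose band 0.40), two neutral mid-Rf bands, and the low-Rf
#' fructooligosaccharide window 0.062-0.163; by default old samples are
#' enriched 1.6x in the low-Rf window and depleted to 0.67x in the simple
#' sugars, mirroring age-driven fructan accumulation.
#'
#' @param n_per_class samples per class (default 6).
#' @param rf_grid decreasing Rf positions in (0, 1).
#' @param class_effects named multiplicative old/young effects, one per grid
#'   band; default as described.
#' @param noise_cv lognormal noise CV (default 0.1).
#' @param baseline baseline band intensities (arbitrary units).
#' @param seed mandatory seed.
#' @return object of class `hptlc_sim_params`.
#' @export
hptlc_sim_params <- function(n_per_class = 6,
                             rf_grid = c(0.57, 0.51, 0.40, 0.30, 0.22,
                                         0.163, 0.129, 0.098, 0.062),
                             class_effects = NULL,
                             noise_cv = 0.1,
                             baseline = NULL,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for the simulator")
  stopifnot(all(rf_grid > 0 & rf_grid < 1), all(diff(rf_grid) < 0),
            noise_cv >= 0, n_per_class >= 1)
  if (is.null(class_effects)) {
    class_effects <- ifelse(rf_grid <= 0.163, 1.6,
                            ifelse(rf_grid %in% c(0.57, 0.51, 0.40), 0.67, 1))
  }
  if (is.null(baseline)) {
    baseline <- 100 * rf_grid / max(rf_grid) + 10  # fades towards low Rf
  }
  stopifnot(length(class_effects) == length(rf_grid),
            all(class_effects > 0),
            length(baseline) == length(rf_grid), all(baseline > 0))
  structure(list(n_per_class = n_per_class, rf_grid = rf_grid,
                 class_effects = class_effects, noise_cv = noise_cv,
                 baseline = baseline, seed = seed),
            class = "hptlc_sim_params")
}

#' Simulate a labelled two-class HPTLC band table
#'
#' @param params an [hptlc_sim_params()] object.
#' @param seed seed; defaults to `params$seed`.
#' @return data.frame `sample`, `label` (`"young"`/`"old"`), then one
#'   `rf_<value>` intensity column per grid band.
#' @export
simulate_hptlc <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "hptlc_sim_params"))
  with_seed(seed, {
    p <- length(params$rf_grid)
    n <- params$n_per_class
    young <- t(vapply(seq_len(n), function(i) {
      params$baseline * lognormal_noise(p, params$noise_cv)
    }, numeric(p)))
    old <- t(vapply(seq_len(n), function(i) {
      params$baseline * params$class_effects *
        lognormal_noise(p, params$noise_cv)
    }, numeric(p)))
    mat <- rbind(young, old)
    colnames(mat) <- sprintf("rf_%g", params$rf_grid)
    cbind(data.frame(sample = sprintf("H%d", seq_len(2 * n)),
                     label = rep(c("young", "old"), each = n),
                     stringsAsFactors = FALSE),
          as.data.frame(mat))
  })
}
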