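#' Fructan structures as rooted residue trees
#'
#' A fructan is modelled as a connected acyclic graph of hexose residues.
#' Every edge records that the *donor* residue attaches through its anomeric
#' carbon (C2 for fructose, C1 for glucose) to a named carbon `position` on the
#' *acceptor*. Fructose residues accept at C1 or C6; glucose accepts at C6
#' (the neo-fructan attachment); the single glucose-donor edge is the sucrose
#' moiety's anomeric-anomeric bond and lands on a fructose C2.
#'
#' A structure may contain at most one glucose. When present it is taken as
#' the root label; otherwise (an F-series fructan) the root is the unique
#' fructose whose anomeric carbon is free.
#'
#' @param residues data.frame with columns `id` (unique character) and
#'   `sugar` (`"glucose"` or `"fructose"`).
#' @param edges data.frame with columns `donor`, `acceptor`, `position`
#'   (`"C1"`, `"C2"` or `"C6"`). May have zero rows for a single residue.
#' @param root optional residue id; defaults to the glucose when present,
#'   else the residue that donates to no-one.
#' @param validate check all structural invariants (default `TRUE`).
#' @return object of class `fructan_structure`.
#' @seealso [census()], [classify_topology()], [assemble_core()]
#' @examples
#' sucrose <- fructan_structure(
#'   residues = data.frame(id = c("G", "F1"),
#'                         sugar = c("glucose", "fructose")),
#'   edges = data.frame(donor = "G", acceptor = "F1", position = "C2")
#' )
#' census(sucrose)
#' @export
fructan_structure <- function(residues, edges, root = NULL, validate = TRUE) {
  residues <- as.data.frame(residues, stringsAsFactors = FALSE)
  if (missing(edges) || is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(donor = character(), acceptor = character(),
                        position = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  }
  if (is.null(root)) {
    glc <- residues$id[residues$sugar == "glucose"]
    if (length(glc) == 1) {
      root <- glc
    } else {
      donors <- edges$donor
      sink <- setdiff(residues$id, donors)
      root <- if (length(sink)) sink[[1]] else residues$id[[1]]
    }
  }
  x <- structure(list(residues = residues, edges = edges, root = root),
                 class = "fructan_structure")
  if (validate) validate_fructan(x)
  x
}

#' Validate a fructan structure
#'
#' Checks the tree invariants: unique ids, at most one glucose, one anomeric
#' donation per residue, legal acceptor positions (fructose C1/C6, glucose C6,
#' C2 only for the glucose-donor sucrose bond), no duplicate occupation of a
#' position, connectivity and acyclicity. Errors name the offending residue.
#'
#' @param x a [fructan_structure()].
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_fructan <- function(x) {
  stopifnot(inherits(x, "fructan_structure"))
  res <- x$residues
  ed <- x$edges
  if (!all(c("id", "sugar") %in% names(res))) {
    stop("residues must have columns 'id' and 'sugar'")
  }
  if (anyDuplicated(res$id)) {
    stop("duplicate residue id: ", res$id[duplicated(res$id)][1])
  }
  if (!all(res$sugar %in% c("glucose", "fructose"))) {
    bad <- res$id[!res$sugar %in% c("glucose", "fructose")][1]
    stop("residue ", bad, " has unknown sugar type")
  }
  glc <- res$id[res$sugar == "glucose"]
  if (length(glc) > 1) {
    stop("a fructan can contain at most one glucose; found ",
         length(glc), " (", paste(glc, collapse = ", "), ")")
  }
  if (nrow(ed)) {
    if (!all(c("donor", "acceptor", "position") %in% names(ed))) {
      stop("edges must have columns 'donor', 'acceptor', 'position'")
    }
    unknown <- setdiff(c(ed$donor, ed$acceptor), res$id)
    if (length(unknown)) stop("edge references unknown residue: ", unknown[1])
    if (any(ed$donor == ed$acceptor)) {
      stop("self-edge at residue ", ed$donor[ed$donor == ed$acceptor][1])
    }
  }
  if (nrow(ed) != nrow(res) - 1L) {
    stop("not a tree: ", nrow(res), " residues require ", nrow(res) - 1L,
         " edges, found ", nrow(ed))
  }
  if (anyDuplicated(ed$donor)) {
    stop("residue ", ed$donor[duplicated(ed$donor)][1],
         " donates through its anomeric carbon more than once")
  }
  sug <- stats::setNames(res$sugar, res$id)
  for (i in seq_len(nrow(ed))) {
    d <- ed$donor[i]; a <- ed$acceptor[i]; p <- ed$position[i]
    if (sug[[d]] == "glucose") {
      if (sug[[a]] != "fructose" || p != "C2") {
        stop("glucose ", d, " may only donate to a fructose C2 ",
             "(the sucrose bond); found position ", p, " on ", a)
      }
    } else if (sug[[a]] == "fructose") {
      if (!p %in% c("C1", "C6")) {
        stop("fructose ", a, " can only accept at C1 or C6 from a fructose ",
             "donor; found position ", p)
      }
    } else { # fructose donating onto the glucose
      if (p != "C6") {
        stop("glucose ", a, " can only accept a fructose at C6; ",
             "found position ", p)
      }
    }
  }
  occ <- paste(ed$acceptor, ed$position)
  if (anyDuplicated(occ)) {
    stop("position already occupied on residue ",
         ed$acceptor[duplicated(occ)][1])
  }
  # connectivity (acyclicity then follows from |E| = |V| - 1)
  if (nrow(res) > 1) {
    adj <- split(c(ed$acceptor, ed$donor), c(ed$donor, ed$acceptor))
    seen <- stats::setNames(logical(nrow(res)), res$id)
    queue <- res$id[1]
    seen[queue] <- TRUE
    while (length(queue)) {
      nb <- unique(unlist(adj[queue], use.names = FALSE))
      queue <- nb[!seen[nb]]
      seen[queue] <- TRUE
    }
    if (!all(seen)) {
      stop("structure is not connected; residue ",
           names(seen)[!seen][1], " is unreachable")
    }
  }
  if (!x$root %in% res$id) stop("root ", x$root, " is not a residue id")
  invisible(x)
}

# Substituted (non-anomeric) positions per residue, as referenced by incoming
# edges: the C2 landing of the sucrose bond is the acceptor fructose's own
# anomeric carbon and does not count as a substitution.
substituted_positions <- function(x) {
  ed <- x$edges
  counted <- ed[ed$position %in% c("C1", "C6"), , drop = FALSE]
  out <- stats::setNames(vector("list", nrow(x$residues)), x$residues$id)
  for (id in names(out)) {
    out[[id]] <- sort(counted$position[counted$acceptor == id])
  }
  out
}

#' Predict the PMAA linkage census of a structure
#'
#' Each residue maps to exactly one of the six linkage classes from its set of
#' substituted positions: fructose with none -> `t_fruf`, \{C1\} -> `b21_fruf`,
#' \{C6\} -> `b26_fruf`, \{C1,C6\} -> `di_fruf`; glucose with none -> `t_glcp`,
#' \{C6\} -> `i_glcp`. Counts always sum to the degree of polymerization.
#'
#' @param structure a valid [fructan_structure()].
#' @return named integer vector over the six canonical classes.
#' @export
census <- function(structure) {
  validate_fructan(structure)
  subs <- substituted_positions(structure)
  sug <- stats::setNames(structure$residues$sugar, structure$residues$id)
  out <- stats::setNames(integer(length(LINKAGE_CLASSES)), LINKAGE_CLASSES)
  for (id in names(subs)) {
    key <- paste(subs[[id]], collapse = ",")
    cls <- if (sug[[id]] == "fructose") {
      switch(key, "t_fruf", "C1" = "b21_fruf", "C6" = "b26_fruf",
             "C1,C6" = "di_fruf")
    } else {
      switch(key, "t_glcp", "C6" = "i_glcp")
    }
    if (is.null(cls)) {
      stop("residue ", id, " has unclassifiable substitution set {", key, "}")
    }
    out[cls] <- out[cls] + 1L
  }
  out
}

#' Degree of polymerization
#'
#' @param structure a valid [fructan_structure()].
#' @return integer number of hexose residues.
#' @export
dp <- function(structure) {
  stopifnot(inherits(structure, "fructan_structure"))
  nrow(structure$residues)
}

#' Classify the topology of a fructan structure
#'
#' Uses the field's standard taxonomy: no glucose -> F-series; terminal
#' glucose without branch residues -> inulin or levan by the dominant fructose
#' linkage; internal glucose without branches -> inulin neo-series; terminal
#' glucose with at least one branch -> graminan; internal glucose with a
#' branch -> agavin.
#'
#' @param structure a valid [fructan_structure()].
#' @return one of `"inulin"`, `"levan"`, `"inulin-neo-series"`, `"graminan"`,
#'   `"agavin"`, `"F-series"`.
#' @export
classify_topology <- function(structure) {
  cen <- census(structure)
  has_glc <- cen[["t_glcp"]] + cen[["i_glcp"]] > 0
  if (!has_glc) return("F-series")
  internal <- cen[["i_glcp"]] > 0
  branched <- cen[["di_fruf"]] > 0
  if (branched) return(if (internal) "agavin" else "graminan")
  if (internal) return("inulin-neo-series")
  if (cen[["b26_fruf"]] > cen[["b21_fruf"]]) "levan" else "inulin"
}

# Necessary-and-sufficient condition for the canonical layout: every edge
# occupies one acceptor position and exactly one edge (the sucrose bond)
# occupies an anomeric position, so counted substitutions = DP - 2, which
# reduces to t_fruf = di_fruf + 1 (terminal glucose) or + 2 (internal).
check_core_feasible <- function(cn, internal) {
  t <- cn[["t_fruf"]]; d <- cn[["di_fruf"]]; b26 <- cn[["b26_fruf"]]
  need <- d + 1L + as.integer(internal)
  if (b26 > 0 && d == 0) {
    stop("infeasible census: ", b26, " levan (2->6) residue(s) with no ",
         "1,6-di branch residue to carry them")
  }
  if (t != need) {
    stop("infeasible census: ", t, " terminal fructose(s) but a tree with ",
         d, " branch residue(s) and ", if (internal) "an internal"
         else "a terminal", " glucose requires exactly ", need,
         " (t_fruf = di_fruf + 1 + [glucose internal])")
  }
  invisible(TRUE)
}

# Split n items into k near-equal chunks (first chunks take the remainder).
even_chunks <- function(n, k) {
  if (k == 0) return(integer())
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

#' Assemble the canonical core structure realizing a linkage census
#'
#' Builds the deterministic canonical layout: glucose at the root attached to
#' the head of a single inulin backbone; branch (1,6-di) residues sit at the
#' glucose-proximal end of the backbone (placed evenly when there are
#' several), each carrying a levan side chain of `b26_fruf` residues capped by
#' a terminal fructose; the backbone is capped by a terminal fructose; with an
#' internal glucose one further terminal fructose occupies the glucose C6.
#' The census of the result reproduces `counts` exactly.
#'
#' Not every count vector is tree-realizable: because each edge consumes one
#' acceptor position and the sucrose bond consumes an anomeric one, any
#' glucose-containing residue tree must satisfy
#' `t_fruf == di_fruf + 1 + [glucose internal]`, and levan residues need a
#' branch residue to attach to. Violations raise an error naming the
#' condition.
#'
#' @param counts linkage census ([as_census()] coercible) with integer counts;
#'   glucose total must be 1.
#' @param glucose_mode `"terminal"` or `"internal"`; defaults to the glucose
#'   class present in `counts`.
#' @return a valid [fructan_structure()].
#' @examples
#' core <- assemble_core(c(t_fruf = 2, b21_fruf = 2, b26_fruf = 1,
#'                         di_fruf = 1, t_glcp = 1))
#' dp(core)               # 7
#' classify_topology(core) # "graminan"
#' @export
assemble_core <- function(counts, glucose_mode = NULL) {
  cn <- as_census(counts)
  if (any(abs(cn - round(cn)) > 1e-8)) {
    stop("assemble_core needs integer counts; use assign_molecules() first")
  }
  cn <- round(cn)
  n_glc <- cn[["t_glcp"]] + cn[["i_glcp"]]
  if (is.null(glucose_mode)) {
    if (n_glc != 1) stop("counts must contain exactly one glucose")
    glucose_mode <- if (cn[["i_glcp"]] == 1) "internal" else "terminal"
  }
  glucose_mode <- match.arg(glucose_mode, c("terminal", "internal"))
  if (n_glc == 0) n_glc <- 1  # mode supplied, glucose implied
  if (n_glc != 1) stop("counts must contain exactly one glucose")
  internal <- glucose_mode == "internal"
  check_core_feasible(cn, internal)

  t <- cn[["t_fruf"]]; b21 <- cn[["b21_fruf"]]
  b26 <- cn[["b26_fruf"]]; d <- cn[["di_fruf"]]

  ids <- character(); sugars <- character()
  edges <- list()
  add_res <- function(prefix, n) {
    if (n == 0) return(character())
    new <- sprintf("%s%d", prefix, seq_len(n) + sum(startsWith(ids, prefix)))
    ids <<- c(ids, new); sugars <<- c(sugars, rep("fructose", n))
    new
  }
  add_edge <- function(donor, acceptor, position) {
    edges[[length(edges) + 1L]] <<- data.frame(
      donor = donor, acceptor = acceptor, position = position,
      stringsAsFactors = FALSE)
  }

  ids <- "G"; sugars <- "glucose"
  # backbone order from the glucose: interleave di residues with even chunks
  # of the 2->1 residues, di first (glucose-proximal), then the backbone cap
  backbone <- character()
  if (d > 0) {
    chunks <- even_chunks(b21, d)
    for (i in seq_len(d)) {
      backbone <- c(backbone, add_res("D", 1), add_res("B", chunks[i]))
    }
  } else {
    backbone <- add_res("B", b21)
  }
  cap <- add_res("T", 1)
  backbone <- c(backbone, cap)

  add_edge("G", backbone[1], "C2")  # sucrose bond
  for (i in seq_along(backbone)[-1]) {
    add_edge(backbone[i], backbone[i - 1], "C1")
  }

  # levan side chains off each di residue's C6, capped with a terminal
  if (d > 0) {
    di_ids <- backbone[startsWith(backbone, "D")]
    arm_sizes <- even_chunks(b26, d)
    for (i in seq_len(d)) {
      arm <- c(di_ids[i], add_res("L", arm_sizes[i]), add_res("T", 1))
      for (j in seq_along(arm)[-1]) add_edge(arm[j], arm[j - 1], "C6")
    }
  }

  if (internal) add_edge(add_res("T", 1), "G", "C6")

  fructan_structure(
    residues = data.frame(id = ids, sugar = sugars, stringsAsFactors = FALSE),
    edges = do.call(rbind, edges)
  )
}

#' Extend a core structure to a target degree of polymerization
#'
#' Two readings of scaling a core to the chromatographically determined
#' maximum DP are offered. `"backbone"` inserts 2->1 fructoses at the
#' glucose-proximal head of the inulin backbone until the target DP is
#' reached, leaving all other arms untouched. `"proportional"` multiplies all
#' non-glucose class counts by `target_dp / dp(core)`, applies the
#' molecule-assignment rounding rules, reconciles the terminal count with tree
#' feasibility (excess terminals become additional 2->1 backbone units, so
#' total residue count is preserved), and reassembles the canonical layout.
#'
#' @param core a valid [fructan_structure()] containing a glucose.
#' @param target_dp integer, at least `dp(core)`.
#' @param mode `"backbone"` (default) or `"proportional"`.
#' @return a valid [fructan_structure()].
#' @export
extend_to_target_dp <- function(core, target_dp,
                                mode = c("backbone", "proportional")) {
  mode <- match.arg(mode)
  validate_fructan(core)
  n0 <- dp(core)
  if (target_dp < n0) {
    stop("target_dp (", target_dp, ") is smaller than the core DP (", n0, ")")
  }
  if (mode == "backbone") {
    k <- target_dp - n0
    if (k == 0) return(core)
    ed <- core$edges
    glc_edge <- which(ed$position == "C2")
    head_id <- if (length(glc_edge)) ed$acceptor[glc_edge[1]] else core$root
    new_ids <- sprintf("X%d", seq_len(k))
    res <- rbind(core$residues,
                 data.frame(id = new_ids, sugar = "fructose",
                            stringsAsFactors = FALSE))
    # splice the new chain between the backbone head and its C1 child
    child <- which(ed$acceptor == head_id & ed$position == "C1")
    chain_edges <- data.frame(
      donor = new_ids,
      acceptor = c(head_id, new_ids[-k]),
      position = "C1", stringsAsFactors = FALSE)
    if (length(child)) {
      # the former C1 child now donates onto the distal new unit
      ed$acceptor[child[1]] <- new_ids[k]
    }
    return(fructan_structure(residues = res, edges = rbind(ed, chain_edges),
                             root = core$root))
  }
  # proportional
  cn <- census(core)
  internal <- cn[["i_glcp"]] > 0
  f <- target_dp / n0
  fr <- c("t_fruf", "b21_fruf", "b26_fruf", "di_fruf")
  scaled <- vapply(cn[fr] * f, assign_one, numeric(1))
  t_req <- scaled[["di_fruf"]] + 1 + as.integer(internal)
  excess <- scaled[["t_fruf"]] - t_req
  if (excess < 0) {
    stop("proportional scaling produced fewer terminals (",
         scaled[["t_fruf"]], ") than the ", scaled[["di_fruf"]],
         " branch residues require (", t_req, ")")
  }
  scaled[["b21_fruf"]] <- scaled[["b21_fruf"]] + excess
  scaled[["t_fruf"]] <- t_req
  counts <- c(as.list(scaled),
              t_glcp = as.integer(!internal), i_glcp = as.integer(internal))
  assemble_core(counts)
}

#' @export
print.fructan_structure <- function(x, ...) {
  cen <- census(x)
  cat(sprintf("<fructan_structure> DP %d, topology: %s\n", dp(x),
              classify_topology(x)))
  nz <- cen[cen > 0]
  cat("  census:", paste(sprintf("%s=%d", LINKAGE_LABELS[names(nz)], nz),
                         collapse = ", "), "\n")
  cat("  ", condensed_formula(x), "\n", sep = "")
  invisible(x)
}

#' Condensed one-line formula for a structure (for logs)
#'
#' Human-readable nesting such as `G[C2:F[C1:F,F]]`; not a parseable
#' interchange format (use [structure_to_json()] for that).
#'
#' @param x a [fructan_structure()].
#' @return character scalar.
#' @export
condensed_formula <- function(x) {
  ed <- x$edges
  sug <- stats::setNames(x$residues$sugar, x$residues$id)
  fmt <- function(id) {
    lab <- if (sug[[id]] == "glucose") "G" else "F"
    inc <- ed[ed$acceptor == id, , drop = FALSE]
    if (!nrow(inc)) return(lab)
    parts <- vapply(order(inc$position), function(i) {
      paste0(inc$position[i], ":", fmt(inc$donor[i]))
    }, character(1))
    paste0(lab, "[", paste(parts, collapse = ","), "]")
  }
  # start from the residue with no outgoing donation (the anomeric sink)
  sink <- setdiff(x$residues$id, ed$donor)
  fmt(sink[[1]])
}

#' Serialize a fructan structure to JSON (schema "fructan-1")
#'
#' @param x a [fructan_structure()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
structure_to_json <- function(x, path = NULL) {
  validate_fructan(x)
  obj <- list(schema = "fructan-1", root = x$root,
              residues = x$residues, edges = x$edges)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a fructan structure from its JSON serialization
#'
#' @param path file path or a JSON string produced by [structure_to_json()].
#' @return a validated [fructan_structure()].
#' @export
structure_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$schema) || obj$schema != "fructan-1") {
    stop("not a fructan-1 structure document")
  }
  edges <- obj$edges
  if (is.null(edges) || !length(edges)) edges <- NULL
  fructan_structure(residues = obj$residues, edges = edges, root = obj$root)
}
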