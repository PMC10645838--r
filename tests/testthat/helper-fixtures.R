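# Hand-built structures, independent of assemble_core(), for use as oracles.

h_structure <- function(sugars, edges) {
  # sugars: named character vector id -> sugar; edges: list of c(donor,
  # acceptor, position)
  ed <- if (length(edges)) {
    do.call(rbind, lapply(edges, function(e) {
      data.frame(donor = e[1], acceptor = e[2], position = e[3],
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  fructan_structure(
    residues = data.frame(id = names(sugars), sugar = unname(sugars),
                          stringsAsFactors = FALSE),
    edges = ed
  )
}

h_sucrose <- function() {
  h_structure(c(G = "glucose", F1 = "fructose"),
              list(c("G", "F1", "C2")))
}

# G-F(2->1)-F(2->1)-F: the DP-4 inulin-type oligosaccharide
h_nystose <- function() {
  h_structure(c(G = "glucose", Fs = "fructose", Fa = "fructose",
                Fb = "fructose"),
              list(c("G", "Fs", "C2"), c("Fa", "Fs", "C1"),
                   c("Fb", "Fa", "C1")))
}

# DP-7 graminan core: terminal glucose, branch residue at the sucrose
# fructose with an inulin chain of two 2->1 units and a one-unit levan
# branch, each arm capped by a terminal fructose.
h_dp7_graminan <- function() {
  h_structure(
    c(G = "glucose", Fd = "fructose", F1 = "fructose", F2 = "fructose",
      Ft1 = "fructose", L1 = "fructose", Ft2 = "fructose"),
    list(c("G", "Fd", "C2"),
         c("F1", "Fd", "C1"), c("F2", "F1", "C1"), c("Ft1", "F2", "C1"),
         c("L1", "Fd", "C6"), c("Ft2", "L1", "C6")))
}

# Brute-force cosine over the full unit-mass grid; deliberately naive and
# independent of cosine_score()'s union-merge implementation.
brute_cosine <- function(a, b) {
  grid <- 1:500
  va <- vb <- numeric(length(grid))
  va[a$mz] <- a$intensity
  vb[b$mz] <- b$intensity
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# Random canonically-realizable census (terminal or internal glucose).
random_census <- function(internal = FALSE) {
  d <- sample(0:3, 1)
  b26 <- if (d > 0) sample(0:4, 1) else 0L
  c(t_fruf = d + 1L + as.integer(internal),
    b21_fruf = sample(0:6, 1),
    b26_fruf = b26,
    di_fruf = d,
    t_glcp = as.integer(!internal),
    i_glcp = as.integer(internal))
}
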