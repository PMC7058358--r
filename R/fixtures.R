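# Catalog of benchmark reaction networks.
#
# Species orderings are frozen per fixture because published weight vectors
# (e.g. xi = (1,1,1,3) for the transcription motif) are order-dependent.

fixture_builders <- list(

  # 4-reaction modification cycle (the motivating example): substrate S is
  # converted through complexes C1, C2 by enzymes E and F
  ptm_reduced = function() parse_network(c(
    "S + E -> C1",
    "C1 -> Y + E",
    "Y + F -> C2",
    "C2 -> S + F"), species = c("S", "E", "C1", "Y", "F", "C2")),

  # full phosphorylation/dephosphorylation cycle with explicit
  # binding/unbinding of both enzymes
  ptm_full = function() parse_network(c(
    "S + E <-> SE",
    "SE -> S+ + E",
    "S+ + F <-> S+F",
    "S+F -> S + F"), species = c("S", "E", "SE", "S+", "F", "S+F")),

  simple_binding = function() parse_network("X + E <-> XE"),

  binding_inflow = function() parse_network(c(
    "X + E <-> XE",
    "0 <-> E")),

  cooperative_binding = function(n = 2) parse_network(c(
    sprintf("%d E <-> En", n),
    "En + X <-> XEn")),

  competitive_binding = function() parse_network(c(
    "E1 + X <-> XE1",
    "X + E2 <-> XE2")),

  three_body_binding = function() parse_network(c(
    "X + E <-> XE",
    "Y + E <-> EY",
    "EY + X <-> XEY",
    "Y + XE <-> XEY")),

  transcription = function() parse_network(c(
    "RNAP + DNA <-> RD",
    "RD -> RNAP + DNA + mRNA",
    "mRNA -> 0"), species = c("RNAP", "DNA", "RD", "mRNA")),

  translation_leak = function() parse_network(c(
    "Rib + mRNA <-> RibmRNA",
    "RibmRNA -> mRNA + P + Rib",
    "RibmRNA -> Rib",
    "P -> 0"), species = c("Rib", "mRNA", "RibmRNA", "P")),

  enzymatic_motif = function() parse_network(c(
    "S + E <-> ES",
    "ES -> E + S+"), species = c("S", "E", "ES", "S+")),

  enzymatic_cycle = function() parse_network(c(
    "S + E <-> SE",
    "SE -> E + S+",
    "S+ -> S"), species = c("S", "E", "SE", "S+")),

  # kinase K consumes ATP: phosphorylation step only
  energy_ptm_basic = function() parse_network(c(
    "K + ATP <-> AK",
    "P + AK <-> PAK",
    "PAK -> PpAmK",
    "PpAmK -> Pp + AmK",
    "AmK <-> K + ADP")),

  # closed energy cycle: ADP recharging and spontaneous dephosphorylation
  energy_ptm_cycle = function() parse_network(c(
    "K + ATP <-> AK",
    "P + AK <-> PAK",
    "PAK -> PpAmK",
    "PpAmK -> Pp + AmK",
    "AmK <-> K + ADP",
    "ADP -> ATP",
    "Pp -> P")),

  # cascade of n modification cycles, each with its own kinase E_i and
  # phosphatase F_i; substrate forms X_0..X_n
  multisite_distinct = function(n = 2) {
    rx <- character(0)
    for (i in seq_len(n) - 1L) {
      rx <- c(rx,
              sprintf("X%d + E%d <-> E%dX%d", i, i, i, i),
              sprintf("E%dX%d -> X%d + E%d", i, i, i + 1L, i),
              sprintf("X%d + F%d <-> F%dX%d", i + 1L, i, i, i + 1L),
              sprintf("F%dX%d -> X%d + F%d", i, i + 1L, i, i))
    }
    species <- c(paste0("X", 0:n),
                 paste0("E", seq_len(n) - 1L), paste0("F", seq_len(n) - 1L),
                 as.vector(rbind(sprintf("E%dX%d", seq_len(n) - 1L, seq_len(n) - 1L),
                                 sprintf("F%dX%d", seq_len(n) - 1L, seq_len(n)))))
    parse_network(rx, species = species)
  },

  # multisite cycle with a processive mechanism: the enzyme stays bound
  # through all n modification steps
  processive = function(n = 2) {
    rx <- c(sprintf("X0 + E <-> EX1"))
    if (n > 1) rx <- c(rx, sprintf("EX%d <-> EX%d", seq_len(n - 1L), seq_len(n - 1L) + 1L))
    rx <- c(rx, sprintf("EX%d -> X%d + E", n, n),
            sprintf("X%d + F <-> FX%d", n, n))
    if (n > 1) rx <- c(rx, sprintf("FX%d <-> FX%d", n:2, n:2 - 1L))
    rx <- c(rx, "FX1 -> X0 + F")
    parse_network(rx)
  },

  # generalized processive cycle: n substrate states, each converted by its
  # own enzyme through a chain of m_i intermediates, cyclically
  all_encompassing = function(ms = c(2, 2)) {
    n <- length(ms)
    rx <- character(0)
    for (i in seq_len(n)) {
      nxt <- if (i == n) 1L else i + 1L
      chain <- sprintf("I%d_%d", i, seq_len(ms[i]))
      rx <- c(rx, sprintf("X%d + E%d <-> %s", i, i, chain[1]))
      if (ms[i] > 1) {
        rx <- c(rx, sprintf("%s <-> %s", chain[-ms[i]], chain[-1]))
      }
      rx <- c(rx, sprintf("%s -> X%d + E%d", chain[ms[i]], nxt, i))
    }
    parse_network(rx)
  },

  # double modification with a distributive mechanism (multistable; the
  # P0 necessary condition fails)
  distributive_double = function() parse_network(c(
    "X0 + E <-> EX0",
    "EX0 -> X1 + E",
    "X1 + F <-> FX1",
    "FX1 -> X0 + F",
    "X1 + E <-> EX1",
    "EX1 -> X2 + E",
    "X2 + F <-> FX2",
    "FX2 -> X1 + F"),
    species = c("X0", "X1", "X2", "E", "F", "EX0", "EX1", "FX1", "FX2")),

  phosphotransfer_motif = function() parse_network(c(
    "Zp + X <-> C",
    "C <-> Xp + Z",
    "Z -> Zp",
    "Xp -> X")),

  phosphotransfer_enzymes = function() parse_network(c(
    "Zp + X <-> C",
    "C <-> Xp + Z",
    "Z + F <-> FZ",
    "FZ -> Zp + F",
    "Xp + E <-> EXp",
    "EXp -> X + E")),

  # relay of n phosphotransfers, driven at X1 and discharged at Xn
  phosphorelay = function(n = 3) {
    rx <- c("X1 -> X1p", sprintf("X%dp -> X%d", n, n))
    for (i in seq_len(n - 1L)) {
      rx <- c(rx,
              sprintf("X%dp + X%d <-> C%d", i, i + 1L, i),
              sprintf("C%d <-> X%dp + X%d", i, i + 1L, i))
    }
    parse_network(rx)
  },

  # T-cell receptor kinetic proofreading chain with N proofreading steps
  kinetic_proofreading = function(N = 2) {
    rx <- c("M + L <-> C0")
    rx <- c(rx, sprintf("C%d -> C%d", 0:(N - 1L), seq_len(N)))
    rx <- c(rx, sprintf("C%d -> M + L", seq_len(N)))
    parse_network(rx, species = c("M", "L", paste0("C", 0:N)))
  },

  # ERK signalling with RKIP regulation
  erk_rkip = function() parse_network(c(
    "Kp + M <-> KpM",
    "KpM -> K + M",
    "E + P <-> EP",
    "EP -> Ep + P",
    "K + R <-> KR",
    "KR + Ep <-> KREp",
    "KREp -> R + E + Kp")),

  # ribosome flow model with n sites: X = occupied, Y = vacant
  ribosome_flow = function(n = 3) {
    rx <- c("Y1 -> X1")
    if (n > 1) {
      rx <- c(rx, sprintf("X%d + Y%d -> Y%d + X%d",
                          seq_len(n - 1L), seq_len(n - 1L) + 1L,
                          seq_len(n - 1L), seq_len(n - 1L) + 1L))
    }
    rx <- c(rx, sprintf("X%d -> Y%d", n, n))
    parse_network(rx)
  },

  # receptor-ligand gated modification cycle: satisfies every necessary
  # condition, but no construction is known to succeed (open case)
  receptor_ptm_open = function() parse_network(c(
    "R + L <-> RL",
    "S + RL <-> C",
    "C -> Sp + RL",
    "Sp -> S"))
)

#' Benchmark network fixtures
#'
#' Deterministic constructors for the catalog of networks analyzed in the
#' package: binding motifs, transcription/translation, enzymatic and
#' modification cycles and cascades, phosphotransfer/phosphorelay,
#' kinetic proofreading, ERK/RKIP and the ribosome flow model.
#'
#' @param id fixture name; see `fixture_names()`.
#' @param ... parameters of parameterized families (`n`, `N`, `ms`).
#' @return a `crn_network`.
#' @examples
#' fixture("ptm_full")
#' fixture("kinetic_proofreading", N = 3)
#' @export
fixture <- function(id, ...) {
  if (!id %in% names(fixture_builders)) {
    stop("unknown fixture '", id, "'; see fixture_names()")
  }
  fixture_builders[[id]](...)
}

#' @rdname fixture
#' @export
fixture_names <- function() names(fixture_builders)

#' Random small network generator
#'
#' Draws `nu` reactions over `n` species with sparse reactant and product
#' complexes (coefficients 0-2, at most two distinct reactants/products).
#' Used for property-style testing of structural invariants.
#'
#' @param n number of species.
#' @param nu number of reactions.
#' @return a `crn_network`.
#' @export
random_network <- function(n = 5, nu = 5) {
  repeat {
    A <- matrix(0, n, nu); B <- matrix(0, n, nu)
    for (j in seq_len(nu)) {
      nr <- sample(0:2, 1); np <- sample(0:2, 1)
      if (nr == 0 && np == 0) np <- 1
      if (nr > 0) A[sample(n, nr), j] <- sample(1:2, nr, replace = TRUE)
      if (np > 0) B[sample(n, np), j] <- sample(1:2, np, replace = TRUE)
    }
    bad <- colSums(A) == 0 & colSums(B) == 0
    if (!any(bad)) {
      return(network_from_matrices(A, B, species = paste0("X", seq_len(n))))
    }
  }
}
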