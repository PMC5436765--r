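# Reaction network of the rat HPA axis: 11 species, 25 mass-action steps.

#' Species of the rat HPA axis network
#'
#' Returns the identifiers of the 11 dynamic species, in the fixed order used
#' by every matrix and state vector in the package: cholesterol (CHOL),
#' corticotrophin releasing hormone (CRH), aldosterone (ALDO),
#' adrenocorticotrophic hormone (ACTH), pregnenolone (PNN), progesterone
#' (PGS), deoxycorticosterone (DCTS), corticosterone (CTS),
#' 17a-hydroxypregnenolone (HPNN), 17a-hydroxyprogesterone (HPGS) and
#' cortisol (CORT).
#'
#' All serialization is by labelled columns, so this ordering is a convention,
#' never load-bearing.
#'
#' @return Character vector of length 11.
#' @export
hpa_species <- function() {
  c("CHOL", "CRH", "ALDO", "ACTH", "PNN", "PGS",
    "DCTS", "CTS", "HPNN", "HPGS", "CORT")
}

#' Default rate constants k1--k25
#'
#' Published values for the 25 reaction steps, in units consistent with molar
#' concentrations and time in minutes: M min^-1 for zeroth-order steps,
#' min^-1 for first order, M^-1 min^-1 for second order and M^-2 min^-1 for
#' third order.
#'
#' @return Named numeric vector `k1` ... `k25`.
#' @export
hpa_rate_constants <- function() {
  k <- c(5.5200e-05, 2.2875e-08, 7.3080e-11, 1.0811e+04, 3.4240e+07,
         7.7371e+00, 3.8686e+00, 1.1606e-02, 1.2000e-03, 1.0000e-05,
         6.1900e-02, 1.2380e-02, 6.1900e-02, 1.5120e+12, 8.4600e+10,
         3.6000e+10, 3.0000e+09, 1.6200e-01, 6.6000e-04, 6.4200e+02,
         7.3800e-02, 1.6200e-01, 1.6200e-01, 1.2840e-02, 1.0000e-05)
  names(k) <- paste0("k", seq_along(k))
  k
}

#' Default initial concentrations (M)
#'
#' The initial state used in all published simulations, at t = 0 (00:00 of
#' day 1).
#'
#' @return Named numeric vector over [hpa_species()].
#' @export
hpa_initial_state <- function() {
  c(CHOL = 3.40e-04, CRH = 1.00e-12, ALDO = 1.50e-09, ACTH = 8.00e-13,
    PNN = 1.00e-10, PGS = 4.00e-08, DCTS = 4.00e-09, CTS = 4.00e-08,
    HPNN = 1.00e-10, HPGS = 4.00e-08, CORT = 1.50e-09)
}

rate_units_for_order <- function(order) {
  switch(as.character(order),
         "0" = "M min-1", "1" = "min-1",
         "2" = "M-1 min-1", "3" = "M-2 min-1",
         stop("unsupported reaction order: ", order))
}

make_reaction <- function(label, reactants, products, rate_constant,
                          forced_by_circadian = FALSE) {
  stopifnot(rate_constant > 0)
  order <- if (length(reactants)) sum(reactants) else 0L
  structure(list(label = label,
                 reactants = reactants,
                 products = products,
                 rate_constant = unname(rate_constant),
                 order = as.integer(order),
                 units = rate_units_for_order(order),
                 forced_by_circadian = forced_by_circadian),
            class = "hpa_reaction")
}

#' Build the rat HPA axis reaction network
#'
#' Constructs the 25-step stoichiometric network with its default (or
#' user-supplied) rate constants. Steps R1--R3 are zeroth-order production of
#' CHOL, CRH and ALDO; R2 is flagged as modulated by the circadian drive so
#' that its effective rate is `k2 * D(t)`. R4 is CRH-stimulated ACTH
#' production: CRH acts catalytically (the rate is `k4 * [CRH]` but CRH is
#' regenerated, so its net stoichiometric change is zero). R5--R13 carry
#' adrenal steroidogenesis from cholesterol through pregnenolone,
#' progesterone, deoxycorticosterone to corticosterone, and the
#' 17a-hydroxylated branch to cortisol. R14 is cubic autocatalysis of
#' corticosterone (positive feedback), R15 aldosterone-mediated
#' autoinhibition, R16/R17 negative feedback of corticosterone on CRH and
#' ACTH, and R18--R25 first-order elimination. Products of elimination and of
#' the feedback steps are unmodelled sinks and never re-enter as reactants.
#'
#' @param k Named numeric vector of 25 positive rate constants
#'   (default [hpa_rate_constants()]).
#' @return An object of class `hpa_network`: list with `species`, `reactions`
#'   (25 `hpa_reaction` objects) and the 11 x 25 net `stoichiometry` matrix
#'   (products minus reactants).
#' @export
build_rat_network <- function(k = hpa_rate_constants()) {
  stopifnot(length(k) == 25, all(k > 0))
  if (is.null(names(k))) names(k) <- paste0("k", 1:25)
  r <- function(...) c(...)
  defs <- list(
    list("R1",  NULL,                  r(CHOL = 1), FALSE),
    list("R2",  NULL,                  r(CRH = 1),  TRUE),
    list("R3",  NULL,                  r(ALDO = 1), FALSE),
    list("R4",  r(CRH = 1),            r(ACTH = 1, CRH = 1), FALSE),
    list("R5",  r(ACTH = 1, CHOL = 1), r(PNN = 1),  FALSE),
    list("R6",  r(PNN = 1),            r(PGS = 1),  FALSE),
    list("R7",  r(PGS = 1),            r(DCTS = 1), FALSE),
    list("R8",  r(DCTS = 1),           r(CTS = 1),  FALSE),
    list("R9",  r(CTS = 1),            r(ALDO = 1), FALSE),
    list("R10", r(PGS = 1),            r(HPGS = 1), FALSE),
    list("R11", r(PNN = 1),            r(HPNN = 1), FALSE),
    list("R12", r(HPNN = 1),           r(HPGS = 1), FALSE),
    list("R13", r(HPGS = 1),           r(CORT = 1), FALSE),
    list("R14", r(DCTS = 1, CTS = 2),  r(CTS = 3),  FALSE),
    list("R15", r(ALDO = 1, CTS = 2),  r(CTS = 1),  FALSE),
    list("R16", r(CRH = 1, CTS = 1),   NULL,        FALSE),
    list("R17", r(ACTH = 1, CTS = 1),  NULL,        FALSE),
    list("R18", r(CHOL = 1),           NULL,        FALSE),
    list("R19", r(CRH = 1),            NULL,        FALSE),
    list("R20", r(ACTH = 1),           NULL,        FALSE),
    list("R21", r(CTS = 1),            NULL,        FALSE),
    list("R22", r(ALDO = 1),           NULL,        FALSE),
    list("R23", r(CORT = 1),           NULL,        FALSE),
    list("R24", r(PNN = 1),            NULL,        FALSE),
    list("R25", r(PGS = 1),            NULL,        FALSE))
  reactions <- lapply(seq_along(defs), function(i) {
    d <- defs[[i]]
    make_reaction(d[[1]], d[[2]], d[[3]], k[[i]], d[[4]])
  })
  species <- hpa_species()
  S <- matrix(0L, nrow = length(species), ncol = length(reactions),
              dimnames = list(species, vapply(reactions, `[[`, "", "label")))
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    for (sp in names(rx$reactants))
      S[sp, j] <- S[sp, j] - as.integer(rx$reactants[[sp]])
    for (sp in names(rx$products))
      S[sp, j] <- S[sp, j] + as.integer(rx$products[[sp]])
  }
  structure(list(species = species, reactions = reactions,
                 stoichiometry = S),
            class = "hpa_network")
}

#' @export
print.hpa_network <- function(x, ...) {
  cat("Rat HPA axis stoichiometric network:",
      length(x$species), "species,", length(x$reactions), "reactions\n")
  for (rx in x$reactions) {
    lhs <- if (length(rx$reactants))
      paste(ifelse(rx$reactants > 1, paste0(rx$reactants, " "), ""),
            names(rx$reactants), sep = "", collapse = " + ") else ""
    rhs <- if (length(rx$products))
      paste(ifelse(rx$products > 1, paste0(rx$products, " "), ""),
            names(rx$products), sep = "", collapse = " + ") else ""
    cat(sprintf("  %-4s %18s -> %-12s k = %.4e %s%s\n", rx$label, lhs, rhs,
                rx$rate_constant, rx$units,
                if (rx$forced_by_circadian) "  [x D(t)]" else ""))
  }
  invisible(x)
}

#' Mass-action flux of a single reaction
#'
#' Flux = k * prod over reactants of concentration^stoichiometry, in
#' M min^-1. For the circadian-forced step (R2) the flux is
#' `k2 * circadian_factor`.
#'
#' @param reaction An `hpa_reaction` from an [build_rat_network()] object.
#' @param state Named nonnegative concentration vector (M).
#' @param circadian_factor Dimensionless positive factor, applied only to
#'   reactions flagged `forced_by_circadian`.
#' @return Flux in M min^-1.
#' @export
reaction_rate <- function(reaction, state, circadian_factor = 1) {
  stopifnot(inherits(reaction, "hpa_reaction"), circadian_factor > 0)
  nm <- names(reaction$reactants)
  if (length(nm)) {
    if (any(!nm %in% names(state)))
      stop("state is missing species: ",
           paste(setdiff(nm, names(state)), collapse = ", "))
    if (any(state[nm] < 0)) stop("negative concentration in state")
  }
  flux <- reaction$rate_constant
  if (reaction$forced_by_circadian) flux <- flux * circadian_factor
  for (sp in nm) flux <- flux * state[[sp]]^reaction$reactants[[sp]]
  unname(flux)
}

#' Vector of all 25 reaction fluxes
#'
#' @inheritParams reaction_rate
#' @param network An `hpa_network`.
#' @return Named numeric vector of fluxes (M min^-1), one per reaction.
#' @export
reaction_rates <- function(network, state, circadian_factor = 1) {
  stopifnot(inherits(network, "hpa_network"))
  v <- vapply(network$reactions, reaction_rate, numeric(1),
              state = state, circadian_factor = circadian_factor)
  names(v) <- vapply(network$reactions, `[[`, "", "label")
  v
}

format_terms <- function(terms) {
  if (!length(terms)) return("")
  paste0(names(terms), ":", as.integer(terms), collapse = "+")
}

parse_terms <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  out <- vapply(kv, function(p) as.integer(p[[2]]), integer(1))
  names(out) <- vapply(kv, `[[`, "", 1)
  out
}

#' Write / read a network as a labelled CSV table
#'
#' One row per reaction with columns `label`, `reactants`, `products`
#' (terms encoded `SPECIES:count+...`), `rate_constant`, `units`,
#' `forced_by_circadian`. Values round-trip at full double precision.
#'
#' @param network An `hpa_network`.
#' @param path File path.
#' @return `write_network_csv` returns `path` invisibly; `read_network_csv`
#'   returns the reconstructed `hpa_network`.
#' @export
write_network_csv <- function(network, path) {
  stopifnot(inherits(network, "hpa_network"))
  df <- data.frame(
    label = vapply(network$reactions, `[[`, "", "label"),
    reactants = vapply(network$reactions,
                       function(r) format_terms(r$reactants), ""),
    products = vapply(network$reactions,
                      function(r) format_terms(r$products), ""),
    rate_constant = sprintf("%.17g", vapply(network$reactions, `[[`,
                                            numeric(1), "rate_constant")),
    units = vapply(network$reactions, `[[`, "", "units"),
    forced_by_circadian = vapply(network$reactions, `[[`, logical(1),
                                 "forced_by_circadian"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rate_constant = "character"))
  reactions <- lapply(seq_len(nrow(df)), function(i) {
    make_reaction(df$label[i], parse_terms(df$reactants[i]),
                  parse_terms(df$products[i]),
                  as.numeric(df$rate_constant[i]),
                  as.logical(df$forced_by_circadian[i]))
  })
  k <- vapply(reactions, `[[`, numeric(1), "rate_constant")
  names(k) <- paste0("k", seq_along(k))
  net <- build_rat_network(k)
  # verify structural agreement with the canonical network
  for (i in seq_along(reactions)) {
    a <- reactions[[i]]; b <- net$reactions[[i]]
    if (!identical(a$label, b$label) ||
        !identical(sort(names(a$reactants)), sort(names(b$reactants))) ||
        !identical(sort(names(a$products)), sort(names(b$products))))
      stop("network file does not describe the rat HPA axis topology (row ",
           i, ")")
  }
  net
}
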