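#' Build a HipBA reaction network
#'
#' Constructs the mass-action reaction network for one of the three
#' regulatory architectures:
#' \describe{
#'   \item{`wild_type`}{the native operon: one promoter with free (`P`),
#'     B2-bound (`Pp`) and AB2A-bound (`Ppp`) states, a shared transcript
#'     `M` translating both HipB and HipA, dimerization, complex
#'     formation/dissociation and degradation. 8 species, 17 reactions.}
#'   \item{`uncoupled`}{hipB and hipA transcribed from two independent
#'     promoters (each with its own three states) into separate transcripts
#'     `M_B` and `M_A`; every rate constant keeps its wild-type value so the
#'     comparison is controlled. 12 species.}
#'   \item{`no_feedback`}{autorepression removed: only the free promoter
#'     state exists and transcribes constitutively at `alpha`; B2 and AB2A
#'     still form and degrade but never bind the promoter. All remaining
#'     rates equal wild type.}
#' }
#'
#' The network is the single source of truth for both backends: the
#' deterministic right-hand side uses fluxes `mult * k * prod(x^order)` and
#' the stochastic engine uses combinatorial propensities
#' `mult * k * prod(x(x-1)...)`, so the two agree in the large-count limit.
#' The per-reaction multiplier is 1/2 for HipB dimerization, complex
#' association and complex dissociation, matching the half factors in the
#' deterministic rate equations (one dimerization event consumes two B; one
#' association event consumes two A and one B2; one dissociation event
#' releases them).
#'
#' @param variant one of `"wild_type"`, `"uncoupled"`, `"no_feedback"`.
#' @param promoter_copies chromosomal copy number of each promoter
#'   (default 1; the uncoupled variant has this many copies of each of its
#'   two promoters).
#'
#' @return An object of class `hipba_network`: species names and roles,
#'   reactant and net stoichiometry matrices (species x reactions), the
#'   rate-constant name and multiplier of each reaction, promoter
#'   conservation groups, and the default initial state (all free promoters,
#'   nothing else).
#'
#' @examples
#' net <- build_network("wild_type")
#' length(net$rate_names)  # 17 reactions
#' net$species             # 8 species
#' @export
build_network <- function(variant = c("wild_type", "uncoupled", "no_feedback"),
                          promoter_copies = 1L) {
  variant <- tryCatch(match.arg(variant), error = function(e)
    stop("unknown variant tag: ", paste(variant, collapse = ", "),
         " (expected wild_type, uncoupled or no_feedback)", call. = FALSE))
  promoter_copies <- as.integer(promoter_copies)
  if (is.na(promoter_copies) || promoter_copies < 1L)
    stop("promoter_copies must be a positive integer", call. = FALSE)

  switch(variant,
    wild_type   = network_wild_type(promoter_copies),
    uncoupled   = network_uncoupled(promoter_copies),
    no_feedback = network_no_feedback(promoter_copies))
}

# internal constructor from a reaction list
make_network <- function(variant, species, roles, reactions, conservations,
                         init) {
  nS <- length(species)
  nR <- length(reactions)
  reactant <- matrix(0L, nS, nR, dimnames = list(species, NULL))
  net <- matrix(0L, nS, nR, dimnames = list(species, NULL))
  rate_names <- character(nR)
  mult <- numeric(nR)
  for (j in seq_len(nR)) {
    rx <- reactions[[j]]
    rate_names[j] <- rx$rate
    mult[j] <- if (is.null(rx$mult)) 1 else rx$mult
    for (nm in names(rx$from)) reactant[nm, j] <- as.integer(rx$from[[nm]])
    net[, j] <- -reactant[, j]
    for (nm in names(rx$to)) net[nm, j] <- net[nm, j] + as.integer(rx$to[[nm]])
  }
  structure(list(
    variant = variant, species = species, roles = roles,
    reactant = reactant, net = net, rate_names = rate_names, mult = mult,
    conservations = conservations, init_default = init),
    class = "hipba_network")
}

rx <- function(rate, from = c(), to = c(), mult = 1)
  list(rate = rate, from = as.list(from), to = as.list(to), mult = mult)

network_wild_type <- function(n) {
  species <- c("P", "Pp", "Ppp", "M", "A", "B", "B2", "AB2A")
  roles <- c(P = "promoter", Pp = "promoter", Ppp = "promoter",
             M = "mrna", A = "protein", B = "protein",
             B2 = "protein", AB2A = "protein")
  reactions <- list(
    rx("alpha",      from = c(P = 1),          to = c(P = 1, M = 1)),
    rx("alpha_B2",   from = c(Pp = 1),         to = c(Pp = 1, M = 1)),
    rx("alpha_AB2A", from = c(Ppp = 1),        to = c(Ppp = 1, M = 1)),
    rx("theta_B2",   from = c(P = 1, B2 = 1),  to = c(Pp = 1)),
    rx("gamma_B2",   from = c(Pp = 1),         to = c(P = 1, B2 = 1)),
    rx("theta_AB2A", from = c(P = 1, AB2A = 1), to = c(Ppp = 1)),
    rx("gamma_AB2A", from = c(Ppp = 1),        to = c(P = 1, AB2A = 1)),
    rx("delta_M",    from = c(M = 1)),
    rx("beta_B",     from = c(M = 1),          to = c(M = 1, B = 1)),
    # HipA translation uses beta_A = 12 (the reaction table's value for
    # HipA translation); amounts produced per mRNA per hour
    rx("beta_A",     from = c(M = 1),          to = c(M = 1, A = 1)),
    rx("delta_B",    from = c(B = 1)),
    rx("delta_A",    from = c(A = 1)),
    rx("beta_B2",    from = c(B = 2),          to = c(B2 = 1), mult = 0.5),
    rx("delta_B2",   from = c(B2 = 1)),
    rx("mu",         from = c(A = 2, B2 = 1),  to = c(AB2A = 1), mult = 0.5),
    rx("mu_R",       from = c(AB2A = 1),       to = c(A = 2, B2 = 1),
       mult = 0.5),
    rx("delta_AB2A", from = c(AB2A = 1))
  )
  init <- stats::setNames(numeric(length(species)), species)
  init["P"] <- n
  make_network("wild_type", species, roles, reactions,
               conservations = list(list(species = c("P", "Pp", "Ppp"),
                                         total = n)),
               init)
}

network_uncoupled <- function(n) {
  species <- c("P_A", "P_Ap", "P_App", "P_B", "P_Bp", "P_Bpp",
               "M_A", "M_B", "A", "B", "B2", "AB2A")
  roles <- c(P_A = "promoter", P_Ap = "promoter", P_App = "promoter",
             P_B = "promoter", P_Bp = "promoter", P_Bpp = "promoter",
             M_A = "mrna", M_B = "mrna",
             A = "protein", B = "protein", B2 = "protein", AB2A = "protein")
  promoter_block <- function(P, Pp, Ppp, M) {
    out <- list(
      rx("alpha",      from = stats::setNames(1, P),
                       to = stats::setNames(c(1, 1), c(P, M))),
      rx("alpha_B2",   from = stats::setNames(1, Pp),
                       to = stats::setNames(c(1, 1), c(Pp, M))),
      rx("alpha_AB2A", from = stats::setNames(1, Ppp),
                       to = stats::setNames(c(1, 1), c(Ppp, M))),
      rx("theta_B2",   from = stats::setNames(c(1, 1), c(P, "B2")),
                       to = stats::setNames(1, Pp)),
      rx("gamma_B2",   from = stats::setNames(1, Pp),
                       to = stats::setNames(c(1, 1), c(P, "B2"))),
      rx("theta_AB2A", from = stats::setNames(c(1, 1), c(P, "AB2A")),
                       to = stats::setNames(1, Ppp)),
      rx("gamma_AB2A", from = stats::setNames(1, Ppp),
                       to = stats::setNames(c(1, 1), c(P, "AB2A")))
    )
    out
  }
  reactions <- c(
    promoter_block("P_A", "P_Ap", "P_App", "M_A"),
    promoter_block("P_B", "P_Bp", "P_Bpp", "M_B"),
    list(
      rx("delta_M", from = c(M_A = 1)),
      rx("delta_M", from = c(M_B = 1)),
      rx("beta_A",  from = c(M_A = 1), to = c(M_A = 1, A = 1)),
      rx("beta_B",  from = c(M_B = 1), to = c(M_B = 1, B = 1)),
      rx("delta_B", from = c(B = 1)),
      rx("delta_A", from = c(A = 1)),
      rx("beta_B2", from = c(B = 2), to = c(B2 = 1), mult = 0.5),
      rx("delta_B2", from = c(B2 = 1)),
      rx("mu", from = c(A = 2, B2 = 1), to = c(AB2A = 1), mult = 0.5),
      rx("mu_R", from = c(AB2A = 1), to = c(A = 2, B2 = 1), mult = 0.5),
      rx("delta_AB2A", from = c(AB2A = 1))
    ))
  init <- stats::setNames(numeric(length(species)), species)
  init[c("P_A", "P_B")] <- n
  make_network("uncoupled", species, roles, reactions,
               conservations = list(
                 list(species = c("P_A", "P_Ap", "P_App"), total = n),
                 list(species = c("P_B", "P_Bp", "P_Bpp"), total = n)),
               init)
}

network_no_feedback <- function(n) {
  species <- c("P", "M", "A", "B", "B2", "AB2A")
  roles <- c(P = "promoter", M = "mrna", A = "protein", B = "protein",
             B2 = "protein", AB2A = "protein")
  reactions <- list(
    rx("alpha",      from = c(P = 1), to = c(P = 1, M = 1)),
    rx("delta_M",    from = c(M = 1)),
    rx("beta_B",     from = c(M = 1), to = c(M = 1, B = 1)),
    rx("beta_A",     from = c(M = 1), to = c(M = 1, A = 1)),
    rx("delta_B",    from = c(B = 1)),
    rx("delta_A",    from = c(A = 1)),
    rx("beta_B2",    from = c(B = 2), to = c(B2 = 1), mult = 0.5),
    rx("delta_B2",   from = c(B2 = 1)),
    rx("mu",         from = c(A = 2, B2 = 1), to = c(AB2A = 1), mult = 0.5),
    rx("mu_R",       from = c(AB2A = 1), to = c(A = 2, B2 = 1), mult = 0.5),
    rx("delta_AB2A", from = c(AB2A = 1))
  )
  init <- stats::setNames(numeric(length(species)), species)
  init["P"] <- n
  make_network("no_feedback", species, roles, reactions,
               conservations = list(list(species = "P", total = n)),
               init)
}

#' @export
print.hipba_network <- function(x, ...) {
  cat("HipBA reaction network, variant '", x$variant, "': ",
      length(x$species), " species, ", length(x$rate_names),
      " reactions\n", sep = "")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

# internal: rate-constant values in reaction order; networks carrying their
# own rate_values (synthetic fixtures) ignore params
reaction_rates <- function(network, params) {
  if (!is.null(network$rate_values))
    return(unname(network$rate_values[network$rate_names]))
  assert_params(params)
  bad <- setdiff(network$rate_names, names(params$value))
  if (length(bad))
    stop("network references unknown rate constant(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  unname(params$value[network$rate_names])
}

# internal: validate a state vector against a network
assert_state <- function(state, network, integer = FALSE) {
  if (length(state) != length(network$species))
    stop("state has length ", length(state), " but network has ",
         length(network$species), " species", call. = FALSE)
  if (any(!is.finite(state)) || any(state < 0))
    stop("species amounts must be finite and nonnegative", call. = FALSE)
  if (integer && any(state != round(state)))
    stop("stochastic states must be integer molecule counts", call. = FALSE)
  invisible(state)
}

#' Serialize a network to JSON
#'
#' Writes a plain JSON description of the network (variant, species list and
#' one record per reaction with reactants, products, rate-constant name and
#' multiplier, plus the numeric rate if `params` is supplied) so that
#' architecture variants can be inspected and diffed.
#'
#' @param network a `hipba_network`.
#' @param params optional `hipba_params`; if given, numeric rate values are
#'   included.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
network_to_json <- function(network, params = NULL, path = NULL) {
  side <- function(stoich_col) {
    idx <- which(stoich_col > 0)
    if (!length(idx)) return("0")
    paste(ifelse(stoich_col[idx] > 1,
                 paste0(stoich_col[idx], " ", network$species[idx]),
                 network$species[idx]), collapse = " + ")
  }
  prod_mat <- network$net + network$reactant
  reactions <- lapply(seq_along(network$rate_names), function(j) {
    r <- list(reactants = side(network$reactant[, j]),
              products = side(prod_mat[, j]),
              rate_constant = network$rate_names[j],
              multiplier = network$mult[j])
    if (!is.null(params)) r$value <- unname(params$value[network$rate_names[j]])
    r
  })
  doc <- list(variant = network$variant, species = network$species,
              promoter_conservation = lapply(network$conservations, function(cv)
                list(species = cv$species, total = cv$total)),
              reactions = reactions)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
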