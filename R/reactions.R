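#' Read the packaged mass-action reaction table
#'
#' The reaction set ships as a plain-text, auditable TSV resource. Each row
#' is one reaction with an event-rate constant `k`: the reaction rate is
#' `r = k * [A] * [B]` for second-order rows (with `r = k * [A]^2` for
#' self-reactions, each event consuming two molecules) and `r = k * [A]` for
#' first-order rows (the radical decay channels, units 1/s).
#'
#' @param file Path to a reaction TSV. Defaults to the table shipped with
#'   the package.
#' @return A data frame with columns `id`, `reactants`, `products`, `k`,
#'   `order` and `flag`.
#' @export
ros_reaction_table <- function(file = system.file("extdata", "reactions.tsv",
                                                  package = "flashros")) {
  rx <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  rx$flag[is.na(rx$flag)] <- ""
  if (anyDuplicated(rx$id)) stop("duplicate reaction ids")
  if (any(rx$k < 0)) stop("negative rate constant in reaction table")
  rx
}

# Parse a "2 A + B" side string into a named integer stoichiometry vector.
parse_side <- function(side) {
  side <- trimws(side)
  if (is.na(side) || side == "") return(integer(0))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- integer(0)
  for (tm in terms) {
    parts <- strsplit(tm, "[ ]+")[[1]]
    if (length(parts) == 2) {
      n <- as.integer(parts[1]); nm <- parts[2]
    } else {
      n <- 1L; nm <- parts[1]
    }
    out[nm] <- (if (nm %in% names(out)) out[[nm]] else 0L) + n
  }
  out
}

#' Build a radiolysis reaction network
#'
#' Assembles the right-hand side of the kinetic system: for every integrated
#' species the derivative is the radiolytic source term `G_i * rho_w * Ddot`
#' plus the mass-action gain/loss terms of all reactions it takes part in.
#' Reactions involving constant pools (water, RH, LH, H+, OH-, Fe2+) have
#' the pool concentration folded into an effective pseudo-first-order
#' constant at build time. Products that are pools are dropped.
#'
#' @param species A [ros_species()] table.
#' @param reactions A reaction table from [ros_reaction_table()] (or a subset
#'   of it, e.g. an empty table for a source-only system).
#' @param lh_routing Fate of the lipid radical L. formed by the
#'   `ROO. + LH -> ROOH + L.` propagation step: `"alkyl"` (default; L.
#'   re-enters the generic carbon-centred radical pool and continues the
#'   peroxidation chain) or `"sink"` (L. is an inert tracked sink).
#' @param h2o2_disprop Include the first-order hydrogen-peroxide
#'   disproportionation channel (default `TRUE`, as tabulated).
#' @param termination_rooh_frac Fraction of peroxyl-radical termination
#'   events (`2 ROO. -> O2 + ROH + RO`) that are scored as ROOH production;
#'   default 0.
#' @return An object of class `ros_network`.
#' @export
build_network <- function(species, reactions = ros_reaction_table(),
                          lh_routing = c("alkyl", "sink"),
                          h2o2_disprop = TRUE,
                          termination_rooh_frac = 0) {
  lh_routing <- match.arg(lh_routing)
  stopifnot(termination_rooh_frac >= 0, termination_rooh_frac <= 1)
  if (!h2o2_disprop) reactions <- reactions[reactions$flag != "h2o2_disprop", ]

  dyn <- species$name[species$role != "pool"]
  pools <- stats::setNames(species$conc[species$role == "pool"],
                           species$name[species$role == "pool"])
  nspec <- length(dyn)
  nrx <- nrow(reactions)
  S <- matrix(0, nspec, nrx, dimnames = list(dyn, reactions$id))
  i1 <- integer(nrx); i2 <- integer(nrx); keff <- numeric(nrx)

  route <- function(nm) if (nm == "L" && lh_routing == "alkyl") "R" else nm

  for (j in seq_len(nrx)) {
    rs <- parse_side(reactions$reactants[j])
    ps <- parse_side(reactions$products[j])
    if (any(!names(rs) %in% species$name) || any(!names(ps) %in% species$name))
      stop("unknown species in reaction ", reactions$id[j])
    if (reactions$k[j] < 0) stop("negative rate constant: ", reactions$id[j])
    dyn_r <- rs[names(rs) %in% dyn]
    pool_r <- rs[!names(rs) %in% dyn]
    k <- reactions$k[j] * prod(pools[names(pool_r)] ^ pool_r)
    ord <- reactions$order[j]
    ndyn_factors <- if (ord == 1) 1L else sum(dyn_r) + 0L
    if (ord == 1 && length(dyn_r) > 1)
      stop("first-order reaction with two dynamic reactants: ",
           reactions$id[j])
    if (length(dyn_r) == 0) {
      # all reactants are pools; constant source channels are not supported
      stop("reaction with no dynamic reactant: ", reactions$id[j])
    }
    # rate factors: first-order rows use one power of the (single) dynamic
    # reactant; second-order rows use two concentration factors in total
    # (pool factors already folded into k).
    if (ord == 1) {
      i1[j] <- match(names(dyn_r)[1], dyn); i2[j] <- 0L
    } else {
      facs <- rep(names(dyn_r), dyn_r)
      n_fac <- 2L - length(pool_r)
      if (n_fac < 1) stop("second-order reaction with no dynamic factor: ",
                          reactions$id[j])
      facs <- facs[seq_len(n_fac)]
      i1[j] <- match(facs[1], dyn)
      i2[j] <- if (length(facs) > 1) match(facs[2], dyn) else 0L
    }
    keff[j] <- k
    for (nm in names(rs)) if (nm %in% dyn)
      S[nm, j] <- S[nm, j] - rs[[nm]]
    for (nm in names(ps)) {
      nm2 <- route(nm)
      if (nm2 %in% dyn) S[nm2, j] <- S[nm2, j] + ps[[nm]]
    }
    if (reactions$id[j] == "roo_roo" && termination_rooh_frac > 0)
      S["ROOH", j] <- S["ROOH", j] + termination_rooh_frac
  }

  structure(list(species = species, dyn = dyn, pools = pools,
                 S = S, k = keff, i1 = i1, i2 = i2,
                 reactions = reactions,
                 lh_routing = lh_routing,
                 h2o2_disprop = h2o2_disprop,
                 termination_rooh_frac = termination_rooh_frac),
            class = "ros_network")
}

#' @export
print.ros_network <- function(x, ...) {
  cat("<ros_network> ", length(x$dyn), " integrated species, ",
      length(x$k), " reactions\n", sep = "")
  cat("  pools:", paste(names(x$pools), signif(x$pools, 3), sep = "=",
                        collapse = ", "), "\n")
  cat("  L. routing:", x$lh_routing,
      "| H2O2 disproportionation:", x$h2o2_disprop, "\n")
  invisible(x)
}

# Radiolytic source vector (mol/L/s per unit dose rate) on the dynamic state.
source_vector <- function(network, yields, rho_w = 1) {
  g <- numeric(length(network$dyn))
  names(g) <- network$dyn
  g[names(yields)] <- yields * 1e-6 * rho_w
  g
}

#' Evaluate the kinetic right-hand side
#'
#' Reference (pure R) evaluation of the concentration derivatives at a given
#' state and instantaneous dose rate: radiolytic source `G_i * rho_w * Ddot`
#' plus mass-action gains and losses. Constant pools have zero derivative by
#' construction (they are not part of the dynamic state).
#'
#' @param network A [build_network()] object.
#' @param state Named (or network-ordered) concentration vector, mol/L.
#' @param rate Instantaneous dose rate, Gy/s.
#' @param yields Primary yields from [primary_yields()].
#' @param rho_w Water density, kg/L.
#' @return Derivative vector (mol/L/s) over the dynamic species.
#' @export
evaluate_rhs <- function(network, state, rate, yields, rho_w = 1) {
  if (length(state) != length(network$dyn))
    stop("state length does not match network dimension")
  y <- as.numeric(state)
  two <- network$i2 > 0
  f1 <- ifelse(two, pmax(y[network$i1], 0), y[network$i1])
  f2 <- ifelse(two, pmax(y[pmax(network$i2, 1)], 0), 1)
  r <- network$k * f1 * f2
  dy <- as.numeric(network$S %*% r) +
    source_vector(network, yields, rho_w) * rate
  names(dy) <- network$dyn
  dy
}

# Initial dynamic state of a network, mol/L.
initial_state <- function(network) {
  sp <- network$species
  stats::setNames(sp$conc[match(network$dyn, sp$name)], network$dyn)
}
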