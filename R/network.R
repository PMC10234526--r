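## Reaction-network construction.
##
## Species bookkeeping: free TFs ("T1", "T2", ...), mRNA ("R") and one species
## per enhancer occupancy state. For a k-site enhancer the 2^k states are named
## <letter><bits>, e.g. A0/A1 for one site, B01 for a two-site enhancer with
## only its second site bound. Site order within an enhancer: all TF 1 sites
## first, then TF 2 sites, etc. Saturation/synergy couple all enhancers, so for
## those regimes the occupancy states live on the joint product space (a single
## conservation group) — this keeps every propensity mass-action of order <= 2.

MAX_SITES_PER_GROUP <- 12L

#' Transcription rate of an occupancy pattern
#'
#' Additive (and sub/superadditive, which differ only in binding kinetics):
#' each enhancer with n bound TF 1 and m bound TF 2 contributes n*r1 + m*r2,
#' summed over enhancers. Saturation: rate `sat_rate` whenever at least one
#' enhancer has at least one bound TF, else 0. Synergy: rate `sat_rate` only
#' when every enhancer has at least one bound TF, else 0.
#'
#' @param occupancy_by_enhancer List of 0/1 vectors, one per enhancer, sites
#'   ordered by TF type as in the matching `site_counts`.
#' @param site_counts List of per-TF site-count vectors, one per enhancer.
#' @param params `rate_parameters`.
#' @param regime Interaction regime.
#' @param sat_rate Rate for saturation/synergy; `NULL` means `params$r[1]`.
#' @return Transcription rate (mRNA/time).
#' @export
transcription_rate <- function(occupancy_by_enhancer, site_counts, params,
                               regime, sat_rate = NULL) {
  regime <- match.arg(regime, REGIMES)
  stopifnot(length(occupancy_by_enhancer) == length(site_counts))
  for (i in seq_along(site_counts))
    if (length(occupancy_by_enhancer[[i]]) != sum(site_counts[[i]]))
      stop("occupancy vector length must equal the enhancer's site count",
           call. = FALSE)
  bound_any <- vapply(occupancy_by_enhancer, function(o) any(o > 0), TRUE)
  if (regime %in% c("saturation", "synergy")) {
    r <- if (is.null(sat_rate)) params$r[1] else sat_rate
    hit <- if (regime == "saturation") any(bound_any) else all(bound_any)
    return(if (hit) r else 0)
  }
  total <- 0
  for (i in seq_along(site_counts)) {
    tf_of_site <- rep(seq_along(site_counts[[i]]), site_counts[[i]])
    total <- total + sum(params$r[tf_of_site] * occupancy_by_enhancer[[i]])
  }
  total
}

## all 0/1 occupancy vectors of length k, in binary counting order
occupancy_states <- function(k) {
  if (k == 0L) return(list(integer(0)))
  g <- as.matrix(do.call(expand.grid, rep(list(0:1), k)))
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

state_name <- function(letter, bits) paste0(letter, paste(bits, collapse = ""))

#' Build the mass-action reaction network for a configuration
#'
#' Translates a declarative [system_config()] into an explicit chemical
#' reaction network: per occupancy state and empty site a bimolecular TF
#' binding reaction (rate kon of the site's TF), per filled site a first-order
#' unbinding (koff), a catalytic mRNA production reaction for every occupancy
#' state with positive transcription rate, constant-rate burst production and
#' first-order degradation per TF, and first-order mRNA degradation.
#' Sub/superadditive modulation of kon/koff is applied here, exactly once,
#' using the system's total enhancer count.
#'
#' @param config A `system_config`.
#' @return A `reaction_network`: list with `species` (data.frame: name, role,
#'   group), `stoich` (species x reactions net-change matrix), `propensity`
#'   (data.frame: order 0/1/2, rate, s1, s2 — species indices of the mass-action
#'   monomial), `reactions` (labels), `groups` (list of species-index vectors,
#'   each an occupancy group that always sums to one copy), `x0` (initial state:
#'   all-empty enhancers, zero TFs and mRNA), and `config`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "system_config"))
  n_enh <- length(config$enhancers)
  params <- apply_rate_modulation(config$params, config$regime, n_enh,
                                  config$d1, config$d2)
  nt <- n_tf_types(params)
  joint <- config$regime %in% c("saturation", "synergy")
  site_counts <- lapply(config$enhancers, as.integer)
  k_each <- vapply(site_counts, sum, 1L)
  if (any(k_each > MAX_SITES_PER_GROUP) ||
      (joint && sum(k_each) > MAX_SITES_PER_GROUP))
    stop("occupancy state space too large: at most ", MAX_SITES_PER_GROUP,
         " sites per conservation group", call. = FALSE)

  species <- data.frame(name = c(paste0("T", seq_len(nt)), "R"),
                        role = c(rep("free_tf", nt), "mrna"),
                        group = NA_integer_, stringsAsFactors = FALSE)
  groups <- list()
  ## per-group site membership: for each group, the enhancer index and TF type
  ## of each site, plus the occupancy state list and species indices
  grp_info <- list()
  add_group <- function(enh_idx) {
    # enh_idx: enhancer indices pooled into this group (1 enhancer, or all)
    tf_of_site <- unlist(lapply(enh_idx, function(i)
      rep(seq_along(site_counts[[i]]), site_counts[[i]])))
    enh_of_site <- unlist(lapply(enh_idx, function(i)
      rep(i, sum(site_counts[[i]]))))
    states <- occupancy_states(length(tf_of_site))
    letter <- LETTERS[enh_idx[1]]
    nm <- vapply(states, function(b) state_name(letter, b), "")
    first <- nrow(species) + 1L
    species <<- rbind(species, data.frame(
      name = nm, role = "enhancer_state", group = length(groups) + 1L,
      stringsAsFactors = FALSE))
    idx <- first:(first + length(states) - 1L)
    groups[[length(groups) + 1L]] <<- idx
    grp_info[[length(grp_info) + 1L]] <<- list(
      enh = enh_idx, tf_of_site = tf_of_site, enh_of_site = enh_of_site,
      states = states, sp = idx)
  }
  if (joint) add_group(seq_len(n_enh)) else
    for (i in seq_len(n_enh)) add_group(i)

  n_sp <- nrow(species)
  tf_sp <- seq_len(nt)
  r_sp <- nt + 1L
  stoich_cols <- list(); prop <- list(); labels <- character(0)
  add_reaction <- function(ds, order, rate, s1 = NA_integer_,
                           s2 = NA_integer_, label = "") {
    if (rate < 0) stop("negative rate constant", call. = FALSE)
    v <- integer(n_sp)
    for (nm in names(ds)) v[as.integer(nm)] <- v[as.integer(nm)] + ds[[nm]]
    stoich_cols[[length(stoich_cols) + 1L]] <<- v
    prop[[length(prop) + 1L]] <<- c(order, rate, s1, s2)
    labels[length(labels) + 1L] <<- label
  }

  for (g in grp_info) {
    k <- length(g$tf_of_site)
    for (si in seq_along(g$states)) {
      bits <- g$states[[si]]
      from <- g$sp[si]
      for (j in seq_len(k)) {
        m <- g$tf_of_site[j]
        to_bits <- bits; to_bits[j] <- 1L - to_bits[j]
        to <- g$sp[which(vapply(g$states, identical, TRUE, to_bits))]
        if (bits[j] == 0L) {            # binding: T_m + state -> state+e_j
          ds <- stats::setNames(c(-1L, -1L, 1L),
                                c(tf_sp[m], from, to))
          add_reaction(ds, 2L, params$kon[m], s1 = tf_sp[m], s2 = from,
                       label = sprintf("bind T%d: %s -> %s", m,
                                       species$name[from], species$name[to]))
        } else {                         # unbinding
          ds <- stats::setNames(c(1L, -1L, 1L), c(tf_sp[m], from, to))
          add_reaction(ds, 1L, params$koff[m], s1 = from,
                       label = sprintf("unbind T%d: %s -> %s", m,
                                       species$name[from], species$name[to]))
        }
      }
      # transcription from this occupancy state
      occ <- if (joint)
        lapply(seq_len(n_enh), function(i) bits[g$enh_of_site == i])
      else {
        o <- lapply(seq_len(n_enh), function(i) integer(sum(site_counts[[i]])))
        o[[g$enh[1]]] <- bits
        o
      }
      rate <- if (joint)
        transcription_rate(occ, site_counts, params, config$regime,
                           config$sat_rate)
      else transcription_rate(occ, site_counts, params, "additive")
      if (rate > 0)
        add_reaction(stats::setNames(1L, r_sp), 1L, rate, s1 = from,
                     label = sprintf("transcribe: %s -> %s + R",
                                     species$name[from], species$name[from]))
    }
  }
  for (m in seq_len(nt)) {
    add_reaction(stats::setNames(params$burst_size[m], tf_sp[m]), 0L,
                 params$burst_rate[m],
                 label = sprintf("burst: 0 -> %d T%d", params$burst_size[m], m))
    add_reaction(stats::setNames(-1L, tf_sp[m]), 1L, params$tf_deg[m],
                 s1 = tf_sp[m], label = sprintf("degrade T%d", m))
  }
  add_reaction(stats::setNames(-1L, r_sp), 1L, params$alpha, s1 = r_sp,
               label = "degrade R")

  stoich <- do.call(cbind, stoich_cols)
  rownames(stoich) <- species$name
  pr <- do.call(rbind, prop)
  propensity <- data.frame(order = as.integer(pr[, 1]), rate = pr[, 2],
                           s1 = as.integer(pr[, 3]), s2 = as.integer(pr[, 4]))
  x0 <- integer(n_sp)
  for (g in grp_info) x0[g$sp[1]] <- 1L   # first state = all sites empty
  names(x0) <- species$name
  structure(list(species = species, stoich = stoich, propensity = propensity,
                 reactions = labels, groups = groups, x0 = x0,
                 params = params, config = config),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network: ", nrow(x$species), " species, ",
      ncol(x$stoich), " reactions, ", length(x$groups),
      " conservation group(s)\n", sep = "")
  cat("Species:", paste(x$species$name, collapse = " "), "\n")
  invisible(x)
}

#' Canonical serialized form of a network
#'
#' A species-relabeling-invariant string: species are renamed canonically
#' (free TFs by TF index, mRNA, occupancy states by their group's sorted
#' position and bit pattern) and reactions sorted. Networks that differ only
#' by enhancer reordering compare equal.
#'
#' @param network A `reaction_network`.
#' @return A single character string.
#' @export
canonical_form <- function(network) {
  sp <- network$species
  # canonical group order: by serialized group reaction signature (site count,
  # then member names stripped of their letter)
  grp_key <- vapply(network$groups, function(g)
    paste0(length(g), ":", paste(sort(sub("^[A-Z]+", "", sp$name[g])),
                                 collapse = ",")), "")
  new_name <- sp$name
  for (rank in seq_along(network$groups)) {
    g <- network$groups[order(grp_key)][[rank]]
    new_name[g] <- paste0("G", rank, "_", sub("^[A-Z]+", "", sp$name[g]))
  }
  rxn <- character(ncol(network$stoich))
  for (j in seq_len(ncol(network$stoich))) {
    nz <- which(network$stoich[, j] != 0L)
    p <- network$propensity[j, ]
    mono <- c(if (!is.na(p$s1)) new_name[p$s1], if (!is.na(p$s2)) new_name[p$s2])
    rxn[j] <- paste0(paste(sort(paste0(new_name[nz], ":",
                                       network$stoich[nz, j])),
                           collapse = ";"),
                     "|", p$order, "|", signif(p$rate, 12), "|",
                     paste(sort(mono), collapse = "*"))
  }
  paste(sort(rxn), collapse = "\n")
}

#' Export a network to SBML
#'
#' Writes a minimal SBML Level 3 document with mass-action kinetic laws and
#' initial amounts (enhancers in the all-empty state, TFs and mRNA at zero).
#'
#' @param network A `reaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "enhancer_system")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$species)))
    xml2::xml_add_child(los, "species", id = network$species$name[i],
                        compartment = "cell",
                        initialAmount = as.character(network$x0[i]),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(ncol(network$stoich))) {
    rx <- xml2::xml_add_child(lor, "reaction", id = sprintf("r%03d", j),
                              reversible = "false")
    nz <- which(network$stoich[, j] != 0L)
    reac <- nz[network$stoich[nz, j] < 0L]
    prod <- nz[network$stoich[nz, j] > 0L]
    p <- network$propensity[j, ]
    # catalytic monomial species that do not change are modifiers
    mono <- stats::na.omit(c(p$s1, p$s2))
    mods <- setdiff(mono, nz)
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in reac)
        xml2::xml_add_child(lr, "speciesReference",
                            species = network$species$name[s],
                            stoichiometry = as.character(-network$stoich[s, j]),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in prod)
        xml2::xml_add_child(lp, "speciesReference",
                            species = network$species$name[s],
                            stoichiometry = as.character(network$stoich[s, j]),
                            constant = "true")
    }
    if (length(mods)) {
      lm <- xml2::xml_add_child(rx, "listOfModifiers")
      for (s in mods)
        xml2::xml_add_child(lm, "modifierSpeciesReference",
                            species = network$species$name[s])
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    factors <- c(as.character(signif(p$rate, 12)),
                 network$species$name[mono])
    if (length(factors) == 1L) {
      xml2::xml_add_child(math, "cn", factors)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      xml2::xml_add_child(ap, "cn", factors[1])
      for (f in factors[-1]) xml2::xml_add_child(ap, "ci", f)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
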