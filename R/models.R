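## Three-population demographic model space.
##
## Conventions (shared with the coalescent engine): deme sizes nu relative to
## the ancestral reference (nuA = 1), time backward in units of 2 Nref
## generations, migration rates in units of 2 Nref m (fraction replaced per
## generation scaled by 2 Nref). Populations: 1 and 2 are sisters splitting at
## T2; population 3 splits from their common ancestor at T1 = T2 + dT, so
## split times are nested by construction. tfrac in (0,1) places the epoch
## boundary of ancient-migration / secondary-contact scenarios at tfrac * T2.

.mig3 <- function(m12 = 0, m21 = m12, m13 = 0, m31 = m13,
                  m23 = 0, m32 = m23) {
  matrix(c(0, m12, m13,
           m21, 0, m23,
           m31, m32, 0), 3, 3, byrow = TRUE)
}

.join <- function(from, to) {
  mv <- diag(3)
  mv[from, ] <- 0
  mv[from, to] <- 1
  mv
}

.epoch <- function(end, nu, mig, move = NULL)
  list(end = end, nu = nu, mig = mig, move = move)

# shared scaffold: recent epochs (list, most recent first, ends < T2),
# then join 2->1 at T2, isolation/ancestral-contact epoch up to T1,
# then join 3->1 and the ancestral epoch
.nested_epochs <- function(p, recent, mig_mid) {
  T1 <- p[["T2"]] + p[["dT"]]
  nu_mid <- c(if ("nu12" %in% names(p)) p[["nu12"]] else 1, 1, p[["nu3"]])
  c(recent,
    list(.epoch(T1, nu_mid, mig_mid, move = .join(3, 1)),
         .epoch(Inf, c(1, 1, 1), .mig3())))
}

.nu123 <- function(p) c(p[["nu1"]], p[["nu2"]], p[["nu3"]])

#' Construct a DemographicModel
#' @param id,family identifiers.
#' @param params named numeric defaults.
#' @param lower,upper named bounds (same names as params).
#' @param builder function(params) returning the epoch list.
#' @param npop number of contemporary populations (default 3).
#' @export
demographicModel <- function(id, family, params, lower, upper, builder,
                             npop = 3L) {
  new("DemographicModel", id = id, family = family, params = params,
      lower = lower[names(params)], upper = upper[names(params)],
      builder = builder, npop = as.integer(npop))
}

.default_bounds <- function(params) {
  lw <- params; up <- params
  for (nm in names(params)) {
    if (startsWith(nm, "nu")) { lw[nm] <- 1e-3; up[nm] <- 50 }
    else if (nm %in% c("T", "T2", "dT")) { lw[nm] <- 1e-4; up[nm] <- 10 }
    else if (startsWith(nm, "m")) { lw[nm] <- 1e-4; up[nm] <- 50 }
    else if (nm == "f") { lw[nm] <- 0.01; up[nm] <- 0.99 }
    else if (nm == "tfrac") { lw[nm] <- 0.05; up[nm] <- 0.95 }
  }
  list(lower = lw, upper = up)
}

.mk_model <- function(id, family, params, builder) {
  b <- .default_bounds(params)
  demographicModel(id, family, params, b$lower, b$upper, builder)
}

#' The shipped three-population model menu
#'
#' Seventeen named configurations over five scenario families:
#' divergence with gene flow (1-4), ancient migration (5-7), secondary
#' contact (8-10), simultaneous split (11-14) and hybrid origin (15-17).
#' Migration subscripts name the deme pair; "sym" rates are shared in both
#' directions.
#'
#' @return named list of \linkS4class{DemographicModel}
#' @export
modelRegistry <- function() {
  base <- c(nu1 = 1, nu2 = 1, nu3 = 1)
  tt <- c(T2 = 0.2, dT = 0.1)
  reg <- list()

  ## (i) divergence with gene flow: migration continuous since each split
  dgf <- function(mig_recent_of, mid_uses_m23) function(p) {
    mig_mid <- if (mid_uses_m23) .mig3(m13 = p[["m23"]]) else .mig3()
    .nested_epochs(p, list(.epoch(p[["T2"]], .nu123(p), mig_recent_of(p),
                                  move = .join(2, 1))), mig_mid)
  }
  reg$m01_dgf_sym_adjacent <- .mk_model(
    "m01_dgf_sym_adjacent", "divergence_with_gene_flow",
    c(base, tt, m12 = 1, m23 = 1),
    dgf(function(p) .mig3(m12 = p[["m12"]], m23 = p[["m23"]]), TRUE))
  reg$m02_dgf_sym_all <- .mk_model(
    "m02_dgf_sym_all", "divergence_with_gene_flow",
    c(base, tt, m12 = 1, m13 = 1, m23 = 1),
    dgf(function(p) .mig3(m12 = p[["m12"]], m13 = p[["m13"]],
                          m23 = p[["m23"]]), TRUE))
  reg$m03_dgf_asym_12 <- .mk_model(
    "m03_dgf_asym_12", "divergence_with_gene_flow",
    c(base, tt, m12f = 1, m12b = 1, m23 = 1),
    dgf(function(p) .mig3(m12 = p[["m12f"]], m21 = p[["m12b"]],
                          m23 = p[["m23"]]), TRUE))
  reg$m04_dgf_sym_12only <- .mk_model(
    "m04_dgf_sym_12only", "divergence_with_gene_flow",
    c(base, tt, m12 = 1),
    dgf(function(p) .mig3(m12 = p[["m12"]]), FALSE))

  ## (ii) ancient migration: gene flow only in [tfrac*T2, T2] (and mid epoch)
  am <- function(mig_old_of, mid_uses_m23) function(p) {
    tb <- p[["tfrac"]] * p[["T2"]]
    mig_mid <- if (mid_uses_m23) .mig3(m13 = p[["m23"]]) else .mig3()
    .nested_epochs(p,
      list(.epoch(tb, .nu123(p), .mig3()),
           .epoch(p[["T2"]], .nu123(p), mig_old_of(p), move = .join(2, 1))),
      mig_mid)
  }
  reg$m05_am_sym_adjacent <- .mk_model(
    "m05_am_sym_adjacent", "ancient_migration",
    c(base, tt, m12 = 1, m23 = 1, tfrac = 0.5),
    am(function(p) .mig3(m12 = p[["m12"]], m23 = p[["m23"]]), TRUE))
  reg$m06_am_sym_12 <- .mk_model(
    "m06_am_sym_12", "ancient_migration",
    c(base, tt, m12 = 1, tfrac = 0.5),
    am(function(p) .mig3(m12 = p[["m12"]]), FALSE))
  reg$m07_am_asym_12 <- .mk_model(
    "m07_am_asym_12", "ancient_migration",
    c(base, tt, m12f = 1, m12b = 1, tfrac = 0.5),
    am(function(p) .mig3(m12 = p[["m12f"]], m21 = p[["m12b"]]), FALSE))

  ## (iii) secondary contact: isolation after the splits, gene flow resumes
  ## in the most recent epoch [0, tfrac*T2]
  sc <- function(mig_contact_of) function(p) {
    tb <- p[["tfrac"]] * p[["T2"]]
    .nested_epochs(p,
      list(.epoch(tb, .nu123(p), mig_contact_of(p)),
           .epoch(p[["T2"]], .nu123(p), .mig3(), move = .join(2, 1))),
      .mig3())
  }
  reg$m08_sc_sym_adjacent <- .mk_model(
    "m08_sc_sym_adjacent", "secondary_contact",
    c(base, tt, m12 = 1, m23 = 1, tfrac = 0.5),
    sc(function(p) .mig3(m12 = p[["m12"]], m23 = p[["m23"]])))
  ## flagship: adjacent secondary contact with symmetric migration after a
  ## shorter isolation; sister pair keeps constant symmetric flow, the
  ## 2-3 contact is recent, the isolated ancestor has its own size nu12.
  ## Seven simplex parameters + profiled theta -> k = 8.
  reg$m09_sc_adjacent_sym <- .mk_model(
    "m09_sc_adjacent_sym", "secondary_contact",
    c(base, nu12 = 0.5, tt, msym = 1),
    function(p) {
      tb <- 0.5 * p[["T2"]]
      .nested_epochs(p,
        list(.epoch(tb, .nu123(p), .mig3(m12 = p[["msym"]], m23 = p[["msym"]])),
             .epoch(p[["T2"]], .nu123(p), .mig3(m12 = p[["msym"]]),
                    move = .join(2, 1))),
        .mig3())
    })
  reg$m10_sc_asym_23 <- .mk_model(
    "m10_sc_asym_23", "secondary_contact",
    c(base, tt, m12 = 1, m23f = 1, m23b = 1, tfrac = 0.5),
    sc(function(p) .mig3(m12 = p[["m12"]], m23 = p[["m23f"]],
                         m32 = p[["m23b"]])))

  ## (iv) simultaneous split: trichotomy at T
  ss <- function(mig_of) function(p) {
    list(.epoch(p[["T"]], .nu123(p), mig_of(p),
                move = {mv <- .join(2, 1); mv[3, ] <- c(1, 0, 0); mv}),
         .epoch(Inf, c(1, 1, 1), .mig3()))
  }
  baseT <- c(base, T = 0.25)
  reg$m11_ss_noflow <- .mk_model(
    "m11_ss_noflow", "simultaneous_split", baseT, ss(function(p) .mig3()))
  reg$m12_ss_sym_adjacent <- .mk_model(
    "m12_ss_sym_adjacent", "simultaneous_split",
    c(baseT, m12 = 1, m23 = 1),
    ss(function(p) .mig3(m12 = p[["m12"]], m23 = p[["m23"]])))
  reg$m13_ss_sym_all <- .mk_model(
    "m13_ss_sym_all", "simultaneous_split",
    c(baseT, m12 = 1, m13 = 1, m23 = 1),
    ss(function(p) .mig3(m12 = p[["m12"]], m13 = p[["m13"]],
                         m23 = p[["m23"]])))
  reg$m14_ss_asym_12 <- .mk_model(
    "m14_ss_asym_12", "simultaneous_split",
    c(baseT, m12f = 1, m12b = 1, m23 = 1),
    ss(function(p) .mig3(m12 = p[["m12f"]], m21 = p[["m12b"]],
                         m23 = p[["m23"]])))

  ## (v) hybrid origin: population 2 founded at T2 by admixture drawing a
  ## fraction f of its lineages from population 1 and 1-f from population 3
  hyb <- function(mig_of) function(p) {
    mv <- diag(3)
    mv[2, ] <- c(p[["f"]], 0, 1 - p[["f"]])
    T1 <- p[["T2"]] + p[["dT"]]
    list(.epoch(p[["T2"]], .nu123(p), mig_of(p), move = mv),
         .epoch(T1, c(p[["nu1"]], 1, p[["nu3"]]), .mig3(),
                move = .join(3, 1)),
         .epoch(Inf, c(1, 1, 1), .mig3()))
  }
  baseH <- c(base, tt, f = 0.5)
  reg$m15_hyb_noflow <- .mk_model(
    "m15_hyb_noflow", "hybrid_origin", baseH, hyb(function(p) .mig3()))
  reg$m16_hyb_sym <- .mk_model(
    "m16_hyb_sym", "hybrid_origin", c(baseH, m12 = 1, m23 = 1),
    hyb(function(p) .mig3(m12 = p[["m12"]], m23 = p[["m23"]])))
  reg$m17_hyb_parents <- .mk_model(
    "m17_hyb_parents", "hybrid_origin", c(baseH, m13 = 1),
    hyb(function(p) .mig3(m13 = p[["m13"]])))

  reg
}

#' Epoch list of a model at given parameters
#' @param model a \linkS4class{DemographicModel}
#' @param params named numeric (defaults to the model defaults)
#' @export
modelEpochs <- function(model, params = model@params) {
  model@builder(params)
}

#' Two-population split model (island/divergence scaffold)
#'
#' Split at time T (2 Nref generations) with optional symmetric migration m
#' (2 Nref m units) since the split.
#' @param nu1,nu2 relative deme sizes.
#' @param T split time.
#' @param m symmetric migration rate.
#' @export
twoPopModel <- function(nu1 = 1, nu2 = 1, T = 0.1, m = 0) {
  p <- c(nu1 = nu1, nu2 = nu2, T = T, m = m)
  demographicModel("two_pop_split", "two_population",
                   p, c(nu1 = 1e-3, nu2 = 1e-3, T = 1e-4, m = 0),
                   c(nu1 = 50, nu2 = 50, T = 10, m = 50),
                   function(p) {
                     mig <- matrix(c(0, p[["m"]], p[["m"]], 0), 2, 2)
                     list(.epoch(p[["T"]], c(p[["nu1"]], p[["nu2"]]), mig,
                                 move = matrix(c(1, 0, 1, 0), 2, 2,
                                               byrow = TRUE)),
                          .epoch(Inf, c(1, 1), matrix(0, 2, 2)))
                   }, npop = 2L)
}

#' Four-population model for ABBA-BABA simulations
#'
#' Topology (((P1,P2)P3)O): sisters 1 and 2 join at T2, population 3 at T1,
#' the outgroup at TO (all backward, 2 Nref generations). Optionally a recent
#' admixture pulse at \code{t_adm} moves a fraction \code{f} of population 2
#' lineages into population 3 (backward), i.e. forward-time introgression
#' P3 -> P2.
#'
#' @param T2,T1,TO nested join times (T2 < T1 < TO).
#' @param f pulse admixture fraction (0 = strict tree).
#' @param t_adm pulse time (< T2).
#' @param nu relative sizes of the four demes.
#' @export
fourPopModel <- function(T2 = 0.1, T1 = 0.15, TO = 0.5, f = 0,
                         t_adm = 0.01, nu = c(1, 1, 1, 1)) {
  stopifnot(t_adm < T2, T2 < T1, T1 < TO)
  p <- c(T2 = T2, T1 = T1, TO = TO, f = f, t_adm = t_adm)
  m0 <- matrix(0, 4, 4)
  join4 <- function(from) {
    mv <- diag(4); mv[from, ] <- 0; mv[from, 1] <- 1; mv
  }
  builder <- function(p) {
    eps <- list()
    if (p[["f"]] > 0) {
      mv <- diag(4)
      mv[2, ] <- c(0, 1 - p[["f"]], p[["f"]], 0)
      eps <- list(.epoch(p[["t_adm"]], nu, m0, move = mv))
    }
    c(eps, list(
      .epoch(p[["T2"]], nu, m0, move = join4(2)),
      .epoch(p[["T1"]], c(nu[1], 1, nu[3], nu[4]), m0, move = join4(3)),
      .epoch(p[["TO"]], c(nu[1], 1, 1, nu[4]), m0, move = join4(4)),
      .epoch(Inf, c(1, 1, 1, 1), m0)))
  }
  demographicModel("four_pop_tree", "abba_baba_demo", p,
                   c(T2 = 1e-4, T1 = 1e-4, TO = 1e-3, f = 0, t_adm = 1e-5),
                   c(T2 = 10, T1 = 10, TO = 20, f = 1, t_adm = 1),
                   builder, npop = 4L)
}

#' Minimal secondary-contact configuration (recovery experiments)
#'
#' Six-parameter member of the secondary-contact family: ancestor sizes fixed
#' at the reference, isolation after both splits, symmetric migration m
#' between both adjacent pairs resuming in the most recent half of the
#' sister-split interval [0, T2/2].
#' @export
secondaryContactModel <- function() {
  p <- c(nu1 = 1, nu2 = 1, nu3 = 1, T2 = 0.2, dT = 0.2, m = 1)
  b <- .default_bounds(p)
  demographicModel("sc_minimal", "secondary_contact", p, b$lower, b$upper,
    function(p) {
      tb <- 0.5 * p[["T2"]]
      .nested_epochs(p,
        list(.epoch(tb, .nu123(p), .mig3(m12 = p[["m"]], m23 = p[["m"]])),
             .epoch(p[["T2"]], .nu123(p), .mig3(), move = .join(2, 1))),
        .mig3())
    })
}

#' Single constant-size population model (used for analytic validation)
#' @export
constantSizeModel <- function() {
  demographicModel("const_1pop", "single_population", c(nu = 1),
                   c(nu = 1e-3), c(nu = 50),
                   function(p) list(.epoch(Inf, c(p[["nu"]], 1, 1), .mig3())),
                   npop = 1L)
}
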