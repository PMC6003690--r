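## Synthetic phantom cohort: three latent spatial WM components with distinct
## quantitative fingerprints, linearly mixed into per-subject parameter maps
## with subject-level variability, planted age/gender effects, map-level
## noise, and a configurable set of missing map entries.

.PHANTOM_PARAMS <- c("R1", "R2", "AD", "RD", "chi_m", "R2star", "MPF")

## Reference fingerprints of the three subtypes (track-, frontal-,
## central-like) over the seven analysis parameters.
.DEFAULT_FINGERPRINTS <- rbind(
  track   = c(R1 = 1.01, R2 = 16.6, AD = 1066, RD = 441, chi_m = -10.4,
              R2star = 21.7, MPF = 12.4),
  frontal = c(R1 = 1.07, R2 = 17.9, AD = 863,  RD = 497, chi_m = -1.3,
              R2star = 21.1, MPF = 13.8),
  central = c(R1 = 0.98, R2 = 17.2, AD = 859,  RD = 482, chi_m = -6.3,
              R2star = 20.4, MPF = 12.8))

## Between-subject SD per parameter (typical column SDs of the reference
## fingerprint table).
.DEFAULT_SUBJECT_SD <- c(R1 = 0.05, R2 = 0.8, AD = 30, RD = 29,
                         chi_m = 7.4, R2star = 0.73, MPF = 0.43)

## Grey-matter-like baseline the components are mixed against.
.DEFAULT_BASELINE <- c(R1 = 0.62, R2 = 12.5, AD = 950, RD = 750,
                       chi_m = 5, R2star = 16, MPF = 7)

#' Specification of a synthetic phantom cohort
#'
#' Collects every knob of the generator: grid, cohort size, component
#' geometry parameters, per-component fingerprints, between-subject SDs,
#' planted covariate effects, map noise, missing entries and the seed.
#' Defaults encode the reference study conditions: 20 subjects, a 32^3 grid
#' at 2 mm, three components carrying the reference subtype fingerprints,
#' ages uniform on 20-58 y with balanced gender, a negative global MPF age
#' slope, opposite-sign R1 age slopes (negative frontal, positive
#' track/central), a gender offset on track-like diffusivity, map noise at
#' 20% of each parameter's between-subtype spread, and 7 missing maps.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_subjects number of subjects.
#' @param fingerprints components x parameters matrix of subtype parameter
#'   values (rownames name the components).
#' @param baseline length-7 vector of non-component (GM-like) tissue values.
#' @param subject_sd per-parameter between-subject SD.
#' @param age_slopes components x parameters matrix of per-year slopes.
#' @param gender_offsets components x parameters matrix of female-minus-male
#'   offsets.
#' @param noise_sd per-parameter additive voxel noise SD; default 20% of the
#'   between-subtype spread.
#' @param missing_entries data.frame with columns `subject`, `param` listing
#'   maps to drop.
#' @param age_range min/max of the uniform age distribution (years).
#' @param seed RNG seed for the cohort.
#' @return a classed list (`PhantomSpec`).
#' @export
phantomSpec <- function(grid_shape = c(32L, 32L, 32L), voxel_size_mm = 2,
                        n_subjects = 20L,
                        fingerprints = .DEFAULT_FINGERPRINTS,
                        baseline = .DEFAULT_BASELINE,
                        subject_sd = .DEFAULT_SUBJECT_SD,
                        age_slopes = NULL, gender_offsets = NULL,
                        noise_sd = NULL,
                        missing_entries = NULL,
                        age_range = c(20, 58),
                        seed = 42L) {
  params <- colnames(fingerprints)
  ncomp <- nrow(fingerprints)
  if (is.null(age_slopes)) {
    age_slopes <- matrix(0, ncomp, length(params),
                         dimnames = list(rownames(fingerprints), params))
    age_slopes[, "MPF"] <- -0.035            # global myelin decline
    if (all(c("track", "frontal", "central") %in% rownames(fingerprints))) {
      age_slopes["frontal", "R1"] <- -0.002  # opposite-sign R1 aging
      age_slopes["track", "R1"] <- 0.002
      age_slopes["central", "R1"] <- 0.002
    }
  }
  if (is.null(gender_offsets)) {
    gender_offsets <- matrix(0, ncomp, length(params),
                             dimnames = list(rownames(fingerprints), params))
    if ("track" %in% rownames(fingerprints)) {
      gender_offsets["track", "AD"] <- 25    # female > male diffusivity
      gender_offsets["track", "RD"] <- 25
    }
  }
  if (is.null(noise_sd)) {
    spread <- apply(fingerprints, 2, function(v) diff(range(v)))
    noise_sd <- 0.2 * spread
  }
  if (is.null(missing_entries)) {
    missing_entries <- data.frame(
      subject = c("s01", "s01", "s01", "s02", "s02", "s02", "s03"),
      param = c("chi_m", "R2star", "MPF", "chi_m", "R2star", "MPF", "R1"),
      stringsAsFactors = FALSE)
  }
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm,
               n_subjects = as.integer(n_subjects), params = params,
               fingerprints = fingerprints, baseline = baseline[params],
               subject_sd = subject_sd[params],
               age_slopes = age_slopes, gender_offsets = gender_offsets,
               noise_sd = noise_sd[params],
               missing_entries = missing_entries,
               age_range = age_range, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

#' Build the phantom component geometry and tissue probability maps
#'
#' Constructs an ellipsoidal brain mask with a WM interior / GM shell, and
#' smooth non-negative component weight fields (anisotropic Gaussians
#' confined to WM): a deep track-like field, a frontal-subcortical field and
#' a central-subcortical field. The builder enforces bounded overlap: the
#' supports (w > 0.5) of any two components may share at most 10% of either,
#' and the in-brain Pearson correlation of any pair must stay below 0.2.
#'
#' @param spec a [phantomSpec()].
#' @return list with `weights` (list of 3D arrays in `[0, 1]`), `pWM`,
#'   `pGM`, `brainMask`.
#' @export
buildComponentGeometry <- function(spec = phantomSpec()) {
  d <- spec$grid_shape
  ncomp <- nrow(spec$fingerprints)
  cx <- (d + 1) / 2
  ax <- arrayInd(seq_len(prod(d)), d)
  semi <- d / 2 - 2
  rho <- sqrt(((ax[, 1] - cx[1]) / semi[1])^2 +
              ((ax[, 2] - cx[2]) / semi[2])^2 +
              ((ax[, 3] - cx[3]) / semi[3])^2)
  brain <- array(rho <= 1, d)
  pWM <- array(stats::plogis((0.66 - rho) / 0.05), d)
  pWM[!brain] <- 0
  pGM <- array((1 - stats::plogis((0.66 - rho) / 0.05)), d)
  pGM[!brain] <- 0
  blob <- function(ctr, sg) {
    w <- exp(-(((ax[, 1] - ctr[1]) / sg[1])^2 +
               ((ax[, 2] - ctr[2]) / sg[2])^2 +
               ((ax[, 3] - ctr[3]) / sg[3])^2) / 2)
    w <- array(w, d) * pWM
    ## flat-topped field: saturate at 1 over the blob core so the component
    ## has a pure region where the fingerprint is attained exactly, and
    ## compactly supported so distant tissue carries strictly zero weight
    w <- pmin(w / (0.55 * max(w)), 1)
    w[w < 0.08] <- 0
    w
  }
  sc <- d / 32                       # geometry scales with the grid
  geoms <- list(
    track   = blob(cx + c(0, -3, -2) * sc, c(5.0, 4.2, 3.0) * sc),
    frontal = blob(cx + c(0, 8.2, 1) * sc, c(5.0, 2.4, 3.8) * sc),
    central = blob(cx + c(0, -2, 6.8) * sc, c(5.5, 4.0, 2.2) * sc))
  weights <- geoms[seq_len(min(ncomp, length(geoms)))]
  if (ncomp > length(geoms))
    stop("default geometry supports at most ", length(geoms), " components")
  ## overlap and correlation guards
  if (length(weights) > 1) {
    for (i in seq_len(length(weights) - 1)) for (j in (i + 1):length(weights)) {
      si <- weights[[i]] > 0.5; sj <- weights[[j]] > 0.5
      ov <- sum(si & sj)
      if (ov > 0.10 * min(sum(si), sum(sj)))
        stop("component supports ", i, " and ", j, " overlap beyond 10%")
      r <- stats::cor(weights[[i]][brain], weights[[j]][brain])
      if (r > 0.2)
        stop("component fields ", i, " and ", j,
             " are spatially correlated (r = ", round(r, 3), " > 0.2)")
    }
  }
  list(weights = weights, pWM = pWM, pGM = pGM, brainMask = brain)
}

#' Generate a synthetic phantom cohort
#'
#' For each subject s and parameter p the generated map is
#' `baseline_p + sum_c w_c(v) (fingerprint_cp - baseline_p) + subject effect
#' + covariate effects + noise` inside the brain and exactly zero outside.
#' The subject effect is a global per-(subject, parameter) offset; age and
#' gender effects enter through the component weights so they are
#' subtype-specific. Output is byte-identical for a fixed spec and seed.
#'
#' @param spec a [phantomSpec()].
#' @param keepTrueMaps store the pre-noise maps in the ground truth (adds
#'   memory; disable for replicate loops).
#' @return a [PhantomCohort-class].
#' @export
generatePhantomCohort <- function(spec = phantomSpec(), keepTrueMaps = FALSE) {
  geo <- buildComponentGeometry(spec)
  d <- spec$grid_shape
  params <- spec$params
  np <- length(params)
  ns <- spec$n_subjects
  ncomp <- length(geo$weights)
  ageMid <- mean(spec$age_range)
  brain <- geo$brainMask
  nb <- sum(brain)
  withSeed(spec$seed, {
    age <- stats::runif(ns, spec$age_range[1], spec$age_range[2])
    gender <- rep(c("M", "F"), length.out = ns)[sample.int(ns)]
    subjEff <- matrix(stats::rnorm(ns * np), ns, np,
                      dimnames = list(NULL, params))
    subjEff <- sweep(subjEff, 2, spec$subject_sd, `*`)
    ids <- sprintf("s%02d", seq_len(ns))
    records <- vector("list", ns)
    trueMaps <- if (keepTrueMaps) vector("list", ns) else NULL
    W <- vapply(geo$weights, function(w) w[brain], numeric(nb))  # nb x ncomp
    for (s in seq_len(ns)) {
      maps <- vector("list", np)
      tm <- if (keepTrueMaps) vector("list", np) else NULL
      for (p in seq_len(np)) {
        fp <- spec$fingerprints[, p]
        base <- spec$baseline[p]
        vals <- base + as.vector(W %*% (fp - base)) +
          as.vector(W %*% (spec$age_slopes[, p] * (age[s] - ageMid))) +
          as.vector(W %*% (spec$gender_offsets[, p] *
                             as.numeric(gender[s] == "F"))) +
          subjEff[s, p]
        vol <- array(0, d)
        vol[brain] <- vals
        if (keepTrueMaps) tm[[p]] <- vol
        noisy <- vals + stats::rnorm(nb, sd = spec$noise_sd[p])
        if (params[p] %in% c("R1", "R2", "R2star")) noisy <- pmax(noisy, 0)
        if (params[p] == "MPF") noisy <- pmin(pmax(noisy, 0), 35)
        vol2 <- array(0, d)
        vol2[brain] <- noisy
        maps[[p]] <- ParameterMap(vol2, params[p], ids[s], spec$voxel_size_mm)
      }
      names(maps) <- params
      if (keepTrueMaps) { names(tm) <- params; trueMaps[[s]] <- tm }
      records[[s]] <- SubjectRecord(ids[s], maps, geo$pWM, geo$pGM)
    }
  })
  covar <- data.frame(subject = ids, age = age, gender = gender,
                      stringsAsFactors = FALSE)
  tracts <- makeTractFixtures(spec, geo)
  ## pure cores: full weight for the component, zero for every other one
  cores <- lapply(seq_along(geo$weights), function(ci) {
    core <- geo$weights[[ci]] > 0.99 & geo$pWM > 0.8
    for (cj in seq_along(geo$weights)[-ci])
      core <- core & geo$weights[[cj]] == 0
    core
  })
  names(cores) <- names(geo$weights)
  gt <- list(weights = geo$weights, cores = cores, pWM = geo$pWM,
             pGM = geo$pGM, brainMask = geo$brainMask,
             fingerprints = spec$fingerprints, subjectEffects = subjEff,
             tracts = tracts, trueMaps = trueMaps)
  cohort <- new("PhantomCohort", records = records, covariates = covar,
                groundTruth = gt, spec = unclass(spec))
  injectMissingEntries(cohort, spec$missing_entries)
}

#' Remove designated maps from a cohort
#'
#' @param cohort a [PhantomCohort-class].
#' @param entries data.frame with columns `subject`, `param`; every entry
#'   must reference an existing map.
#' @return the cohort with the listed maps removed. Subjects left with no
#'   maps are flagged in `groundTruth(cohort)$unusableSubjects`.
#' @export
injectMissingEntries <- function(cohort, entries) {
  if (is.null(entries) || nrow(entries) == 0L) return(cohort)
  recs <- cohort@records
  ids <- vapply(recs, subjectId, character(1))
  for (k in seq_len(nrow(entries))) {
    i <- match(entries$subject[k], ids)
    if (is.na(i) || !entries$param[k] %in% names(recs[[i]]@maps))
      stop("unknown missing entry: ", entries$subject[k], " / ",
           entries$param[k])
    recs[[i]]@maps[[entries$param[k]]] <- NULL
  }
  cohort@records <- recs
  nleft <- vapply(recs, function(r) length(r@maps), integer(1))
  cohort@groundTruth$unusableSubjects <- ids[nleft == 0L]
  cohort
}

#' Synthetic tract fixtures
#'
#' Two tube-shaped pseudo-tracts standing in for a tractography atlas
#' (synthetic; no anatomical meaning): `crossing` runs through the
#' territories of the first two components, `confined` stays inside the
#' first component's territory.
#'
#' @param spec a [phantomSpec()].
#' @param geometry optional precomputed [buildComponentGeometry()] output.
#' @return named list of logical 3D arrays.
#' @export
makeTractFixtures <- function(spec = phantomSpec(), geometry = NULL) {
  if (is.null(geometry)) geometry <- buildComponentGeometry(spec)
  d <- spec$grid_shape
  ax <- arrayInd(seq_len(prod(d)), d)
  cx <- (d + 1) / 2
  sc <- d / 32
  tube <- function(p0, p1, radius) {
    ## distance from the segment p0 -> p1
    v <- p1 - p0
    L2 <- sum(v^2)
    t <- pmin(pmax(((ax[, 1] - p0[1]) * v[1] + (ax[, 2] - p0[2]) * v[2] +
                      (ax[, 3] - p0[3]) * v[3]) / L2, 0), 1)
    dx <- ax[, 1] - (p0[1] + t * v[1])
    dy <- ax[, 2] - (p0[2] + t * v[2])
    dz <- ax[, 3] - (p0[3] + t * v[3])
    array(sqrt(dx^2 + dy^2 + dz^2) <= radius, d)
  }
  w <- geometry$weights
  crossing <- tube(cx + c(0, -3, -2) * sc, cx + c(0, 9, 1) * sc, 1.8 * sc[1])
  confined <- tube(cx + c(-3, -2, -2) * sc, cx + c(3, -1, -2) * sc, 1.5 * sc[1])
  crossing <- crossing & geometry$brainMask
  confined <- confined & (w[[1]] > 0.3)
  list(crossing = crossing, confined = confined)
}

#' Simulate raw acquisition volumes from a subject's parameter maps
#'
#' Applies the package's forward models to a subject's true parameter maps:
#' the multi-echo gradient-echo stack from R2*, the VFA pair from R1, the
#' AFI pair from the B1 field, the MT-weighted/reference pair from R1 and
#' MPF (with B0/B1), the pSSFP pair from R2, and the DWI set from AD/RD
#' (axially symmetric tensor). Sequences whose prerequisite maps are absent
#' are skipped with a warning.
#'
#' @param record a [SubjectRecord-class].
#' @param sequences subset of `c("mgre", "vfa", "afi", "mt", "pssfp", "dti")`.
#' @param b0_field,b1_field optional 3D arrays of field offsets; defaults are
#'   homogeneous (0 Hz, 1.0).
#' @param s0 proton-density scale of the simulated signals.
#' @return named list of raw volume sets (arrays / lists of arrays).
#' @export
simulateRawSignals <- function(record,
                               sequences = c("mgre", "vfa", "afi", "mt",
                                             "pssfp", "dti"),
                               b0_field = NULL, b1_field = NULL, s0 = 100) {
  stopifnot(is(record, "SubjectRecord"))
  maps <- record@maps
  d <- dim(record@pWM)
  b0v <- b0_field %||% array(0, d)
  b1v <- b1_field %||% array(1, d)
  brain <- record@pWM + record@pGM > 0.01
  out <- list()
  need <- function(p, seqname) {
    if (p %in% names(maps)) return(TRUE)
    warning("skipping ", seqname, ": prerequisite map ", p, " missing")
    FALSE
  }
  zeroOutside <- function(v) { v[!brain] <- 0; v }
  if ("mgre" %in% sequences && need("R2star", "mgre")) {
    pr <- mgreParams()
    r2s <- maps$R2star@data
    stack <- array(0, c(d, length(pr$echo_times_ms)))
    for (e in seq_along(pr$echo_times_ms)) {
      v <- s0 * exp(-r2s * pr$echo_times_ms[e] / 1000)
      stack[, , , e] <- zeroOutside(v)
    }
    out$mgre <- list(stack = stack, params = pr)
  }
  if ("vfa" %in% sequences && need("R1", "vfa")) {
    pr <- vfaParams()
    t1 <- 1 / maps$R1@data
    lo <- spgrSignal(t1, pr$tr_ms, pr$flip_angles_deg[1] * b1v, s0)
    hi <- spgrSignal(t1, pr$tr_ms, pr$flip_angles_deg[2] * b1v, s0)
    out$vfa <- list(s_low = zeroOutside(lo), s_high = zeroOutside(hi),
                    params = pr)
  }
  if ("afi" %in% sequences) {
    pr <- afiParams()
    ratio <- afiSignalRatio(pr$nominal_fa_deg * b1v, pr$n)
    s1 <- array(s0, d)
    out$afi <- list(s1 = zeroOutside(s1), s2 = zeroOutside(s1 * ratio),
                    params = pr)
  }
  if ("mt" %in% sequences && need("R1", "mt") && need("MPF", "mt")) {
    pr <- mtParams()
    f <- as.vector(maps$MPF@data) / 100
    ratio <- mtSignalRatio(f, as.vector(1 * maps$R1@data),
                           as.vector(b0v), as.vector(b1v), pr)
    ref <- array(s0, d)
    mt <- array(s0 * ratio, d)
    ## two-echo phase volumes encoding the B0 field
    dte <- diff(pr$te_pair_ms) / 1000
    ph1 <- array(0, d)
    ph2 <- array(wrapPhase(2 * pi * b0v * dte), d)
    out$mt <- list(mt_img = zeroOutside(mt), ref_img = zeroOutside(ref),
                   phase_te1 = ph1, phase_te2 = ph2, params = pr)
  }
  if ("pssfp" %in% sequences && need("R2", "pssfp")) {
    pr <- pssfpParams()
    t2 <- 1 / maps$R2@data
    ## tabulated forward evaluation (same steady-state relation the fitter
    ## inverts); assumed global T1
    tab <- pssfpRatioTable(pr)
    s2v <- array(s0, d)
    logt2 <- log(pmin(pmax(t2, min(tab$t2)), max(tab$t2)))
    b1c <- pmin(pmax(as.vector(b1v), min(tab$b1)), max(tab$b1))
    jlo <- pmin(pmax(findInterval(b1c, tab$b1), 1L), length(tab$b1) - 1L)
    wgt <- (b1c - tab$b1[jlo]) / (tab$b1[jlo + 1L] - tab$b1[jlo])
    rat <- rep(NA_real_, length(t2))
    for (j in seq_len(length(tab$b1) - 1L)) {
      sel <- which(jlo == j)
      if (!length(sel)) next
      rl <- stats::approx(log(tab$t2), tab$ratio[, j], xout = logt2[sel])$y
      rh <- stats::approx(log(tab$t2), tab$ratio[, j + 1L], xout = logt2[sel])$y
      rat[sel] <- (1 - wgt[sel]) * rl + wgt[sel] * rh
    }
    out$pssfp <- list(s_inc1 = zeroOutside(array(s0 * rat, d)),
                      s_inc2 = s2v * as.numeric(brain), params = pr)
  }
  if ("dti" %in% sequences && need("AD", "dti") && need("RD", "dti")) {
    pr <- dtiParams()
    ad <- as.vector(maps$AD@data); rd <- as.vector(maps$RD@data)
    sig <- dtiSignals(cbind(pmax(ad, rd), rd, rd), NULL, pr, s0)
    dwi <- array(0, c(d, nrow(pr$bvecs)))
    for (k in seq_len(nrow(pr$bvecs))) dwi[, , , k] <- zeroOutside(array(sig[, k], d))
    out$dti <- list(dwi = dwi, params = pr)
  }
  out
}
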