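# Compilation of named divergence/hybridization scenarios into
# piecewise-constant structured-coalescent configurations.
#
# Conventions follow the usual diffusion-based JAFS machinery: deme sizes
# nu are relative to the ancestral reference size Nref, times are in
# units of 2*Nref generations, and a scaled migration rate M denotes a
# per-lineage backward jump rate of M/2 per unit time.  theta is a free
# multiplier profiled out of the likelihood, so expected spectra are
# computed per unit theta.

TWO_POP_MODELS <- c("SI", "IM", "AM", "SC",
                    "SIG", "IMG", "AMG", "SCG",
                    "IM2m", "AM2m", "SC2m",
                    "IM2mG", "AM2mG", "SC2mG")
THREE_POP_MODELS <- c("HS", "HSp1", "HSp2", "HS2p", "SGF1", "SGF2")

N_GROWTH_STEPS <- 16L   # piecewise-constant discretization of exponential growth

new_schedule <- function(n_demes, seg_end, nu, mig, events = list()) {
  stopifnot(length(seg_end) == nrow(nu), is.matrix(nu))
  if (any(diff(seg_end) <= 0)) abort("segment end times must strictly increase")
  if (!is.infinite(seg_end[length(seg_end)]))
    abort("the oldest segment must extend to infinity")
  if (any(nu <= 0)) abort("deme sizes must be positive")
  if (any(mig < 0)) abort("migration rates must be non-negative")
  ev <- if (length(events)) {
    list(time = vapply(events, `[[`, 0, "time"),
         type = vapply(events, `[[`, 0L, "type"),
         a = vapply(events, `[[`, 0L, "a"),
         b = vapply(events, `[[`, 0L, "b"),
         c = vapply(events, function(e) e$c %||% 0L, 0L),
         f = vapply(events, function(e) e$f %||% 0, 0))
  } else {
    list(time = numeric(0), type = integer(0), a = integer(0),
         b = integer(0), c = integer(0), f = numeric(0))
  }
  structure(list(n_demes = as.integer(n_demes), seg_end = seg_end,
                 nu = nu, mig = mig,
                 ev_time = ev$time, ev_type = ev$type,
                 ev_a = ev$a, ev_b = ev$b, ev_c = ev$c, ev_f = ev$f),
            class = "coal_schedule")
}

# events use 1-based demes at the R level; convert for the C++ engine
pack_schedule <- function(s) {
  list(n_demes = s$n_demes, seg_end = s$seg_end, nu = s$nu, mig = s$mig,
       ev_time = s$ev_time, ev_type = s$ev_type,
       ev_a = s$ev_a - 1L, ev_b = s$ev_b - 1L,
       ev_c = pmax(s$ev_c - 1L, 0L), ev_f = s$ev_f)
}

check_params <- function(model, p, required) {
  p <- unlist(p)
  missing <- setdiff(required, names(p))
  extra <- setdiff(names(p), required)
  if (length(missing) || length(extra))
    abort(sprintf(
      "parameter mismatch for model %s: %s%s",
      model,
      if (length(missing)) paste0("missing {", paste(missing, collapse = ", "), "} ") else "",
      if (length(extra)) paste0("unexpected {", paste(extra, collapse = ", "), "}") else ""
    ))
  if (any(p[grepl("^nu", names(p))] <= 0)) abort("sizes must be positive")
  if (any(p[grepl("^(M|me|m[0-9])", names(p))] < 0)) abort("migration rates must be non-negative")
  if (any(p[grepl("^T", names(p))] <= 0)) abort("times must be positive")
  for (fr in intersect(c("P", "O", "f"), names(p)))
    if (p[[fr]] < 0 || p[[fr]] > 1) abort(sprintf("%s must lie in [0, 1]", fr))
  as.list(p)
}

#' Free parameters of each demographic model
#'
#' The composite-likelihood scale parameter theta is profiled
#' analytically and is not counted.  Growth variants reuse their base
#' model's parameters (each daughter deme grows exponentially from the
#' ancestral size to its present size), so they add none.
#'
#' @param model Model name.
#' @return Character vector of parameter names; its length is the `k`
#'   used in AIC.
#' @export
model_params <- function(model) {
  base <- sub("G$", "", model)
  pars <- switch(base,
    SI = c("nu1", "nu2", "Ts"),
    IM = c("nu1", "nu2", "M12", "M21", "Ts"),
    AM = c("nu1", "nu2", "M12", "M21", "Ts", "Tam"),
    SC = c("nu1", "nu2", "M12", "M21", "Ts", "Tsc"),
    IM2m = c("nu1", "nu2", "M12", "M21", "me12", "me21", "Ts", "P", "O"),
    AM2m = c("nu1", "nu2", "M12", "M21", "me12", "me21", "Ts", "Tam", "P", "O"),
    SC2m = c("nu1", "nu2", "M12", "M21", "me12", "me21", "Ts", "Tsc", "P", "O"),
    HS = c("nu1", "nu2", "nu3", "Ts", "Th", "f"),
    HSp1 = c("nu1", "nu2", "nu3", "Ts", "Th", "f", "m13", "m31"),
    HSp2 = c("nu1", "nu2", "nu3", "Ts", "Th", "f", "m23", "m32"),
    HS2p = c("nu1", "nu2", "nu3", "Ts", "Th", "f", "m13", "m31", "m23", "m32"),
    SGF1 = c("nu1", "nu2", "nu3", "Ts", "Th", "m13", "m31", "m23", "m32"),
    SGF2 = c("nu1", "nu2", "nu3", "Ts", "Th", "m13", "m31", "m23", "m32"),
    abort(sprintf("unknown model: %s", model))
  )
  pars
}

# growth discretization: sizes nu_end at t = 0 shrinking exponentially
# back to 1 at t = Ts; returns boundaries and per-step sizes (geometric
# midpoint of the exponential trajectory within each step)
growth_steps <- function(nu_end, Ts, n_steps = N_GROWTH_STEPS) {
  edges <- seq(0, Ts, length.out = n_steps + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  sizes <- vapply(nu_end, function(nu) nu^(1 - mid / Ts), numeric(n_steps))
  list(edges = edges[-1], sizes = matrix(sizes, nrow = n_steps))
}

mig2 <- function(M12, M21) {
  # per-lineage backward rates: deme1 -> deme2 at M12/2, deme2 -> deme1 at M21/2
  matrix(c(0, M21 / 2, M12 / 2, 0), 2, 2)
}

assemble_two_pop <- function(p, M12, M21, mig_on, growth) {
  # mig_on: function(t_mid) -> TRUE if migration is active at that time
  Ts <- p$Ts
  if (growth) {
    gs <- growth_steps(c(p$nu1, p$nu2), Ts)
    ends <- gs$edges
    nus <- gs$sizes
  } else {
    ends <- Ts
    nus <- matrix(c(p$nu1, p$nu2), 1, 2)
  }
  # split further at migration on/off boundaries
  bounds <- sort(unique(c(ends, attr(mig_on, "breaks"))))
  bounds <- bounds[bounds <= Ts + 1e-12]
  nseg <- length(bounds) + 1L
  nu <- matrix(1, nseg, 2)
  mig <- array(0, c(nseg, 2, 2))
  starts <- c(0, bounds)
  for (s in seq_len(length(bounds))) {
    tm <- (starts[s] + bounds[s]) / 2
    step <- if (growth) which.max(gs$edges >= bounds[s] - 1e-12) else 1L
    nu[s, ] <- if (growth) gs$sizes[step, ] else c(p$nu1, p$nu2)
    if (mig_on(tm)) mig[s, , ] <- mig2(M12, M21)
  }
  # ancestral segment: one deme of size 1, no migration
  seg_end <- c(bounds, Inf)
  events <- list(list(time = Ts, type = 1L, a = 2L, b = 1L))
  new_schedule(2L, seg_end, nu, mig, events)
}

#' Compile a two-population divergence scenario
#'
#' Supported models: strict isolation (`SI`), isolation with migration
#' (`IM`), ancient migration (`AM`, gene flow only during the `Tam`
#' interval adjacent to the split), secondary contact (`SC`, gene flow
#' only during the most recent `Tsc`); `G` suffixes add exponential
#' growth of each daughter deme from the ancestral size to its present
#' size; `2m` suffixes add a second class of loci (genomic proportion
#' `P`) whose migration rates are `me12`/`me21` instead of `M12`/`M21`,
#' plus the orientation parameter `O` applied to the combined spectrum.
#'
#' @param model Model name, one of `r paste(TWO_POP_MODELS, collapse = ", ")`.
#' @param p Named list (or vector) with exactly the parameters of
#'   [model_params()] for that model; anything missing or extraneous is
#'   an error.
#' @return A `scenario` object: a weighted list of coalescent schedules
#'   plus the orientation parameter.
#' @export
compile_two_pop <- function(model, p) {
  model <- match.arg(model, TWO_POP_MODELS)
  p <- check_params(model, p, model_params(model))
  base <- sub("G$", "", model)
  growth <- grepl("G$", model)
  two_m <- grepl("2m", base)
  stem <- sub("2m", "", base)
  if (stem == "AM" && p$Tam >= p$Ts)
    abort("AM models need Tam < Ts")
  if (stem == "SC" && p$Tsc >= p$Ts)
    abort("SC models need Tsc < Ts")
  mig_on <- switch(stem,
    SI = structure(function(t) FALSE, breaks = numeric(0)),
    IM = structure(function(t) TRUE, breaks = numeric(0)),
    AM = structure(function(t) t >= p$Ts - p$Tam, breaks = p$Ts - p$Tam),
    SC = structure(function(t) t < p$Tsc, breaks = p$Tsc)
  )
  classes <- if (two_m) {
    list(
      list(schedule = assemble_two_pop(p, p$M12, p$M21, mig_on, growth),
           weight = 1 - p$P),
      list(schedule = assemble_two_pop(p, p$me12, p$me21, mig_on, growth),
           weight = p$P)
    )
  } else {
    M12 <- p$M12 %||% 0; M21 <- p$M21 %||% 0
    list(list(schedule = assemble_two_pop(p, M12, M21, mig_on, growth),
              weight = 1))
  }
  structure(list(model = model, params = p, classes = classes,
                 O = if (two_m) p$O else 1),
            class = "scenario")
}

#' Compile a three-population hybrid-origin scenario
#'
#' Deme 1 and deme 2 are the parental lineages (split at `Ts`); deme 3 is
#' the putative hybrid taxon.  In hybrid-speciation models (`HS*`) deme 3
#' is founded at `Th` by an admixture pulse drawing each lineage from
#' parent 1 with probability `f` and parent 2 otherwise; `HSp1`/`HSp2`
#' add continuous gene flow between the hybrid and parent 1 / parent 2
#' only, and `HS2p` with both.  In secondary-gene-flow models deme 3
#' splits from parent 1 (`SGF1`) or parent 2 (`SGF2`) at `Th` and then
#' exchanges genes with both parents.  The parental demes do not exchange
#' migrants in these models; hybrid-parent rates `m13`, `m31`, `m23`,
#' `m32` follow the into-deme-from-deme convention of the two-population
#' models.
#'
#' @param model One of `r paste(THREE_POP_MODELS, collapse = ", ")`.
#' @param p Named list with exactly [model_params()]`(model)`; requires
#'   `Th < Ts`.
#' @return A `scenario` object.
#' @export
compile_three_pop <- function(model, p) {
  model <- match.arg(model, THREE_POP_MODELS)
  p <- check_params(model, p, model_params(model))
  if (p$Th >= p$Ts)
    abort("hybrid-origin time Th must predate the parental split: Th < Ts")
  m13 <- p$m13 %||% 0; m31 <- p$m31 %||% 0
  m23 <- p$m23 %||% 0; m32 <- p$m32 %||% 0
  nseg <- 3L
  seg_end <- c(p$Th, p$Ts, Inf)
  nu <- rbind(c(p$nu1, p$nu2, p$nu3),
              c(p$nu1, p$nu2, 1),
              c(1, 1, 1))
  mig <- array(0, c(nseg, 3, 3))
  # backward per-lineage rates in the recent segment only
  mig[1, 1, 3] <- m31 / 2   # lineage in deme1 traces to deme3
  mig[1, 3, 1] <- m13 / 2
  mig[1, 2, 3] <- m32 / 2
  mig[1, 3, 2] <- m23 / 2
  events <- list()
  if (grepl("^HS", model)) {
    events[[1]] <- list(time = p$Th, type = 2L, a = 3L, b = 1L, c = 2L, f = p$f)
  } else if (model == "SGF1") {
    events[[1]] <- list(time = p$Th, type = 1L, a = 3L, b = 1L)
  } else {
    events[[1]] <- list(time = p$Th, type = 1L, a = 3L, b = 2L)
  }
  events[[2]] <- list(time = p$Ts, type = 1L, a = 2L, b = 1L)
  sched <- new_schedule(3L, seg_end, nu, mig, events)
  structure(list(model = model, params = p,
                 classes = list(list(schedule = sched, weight = 1)), O = 1),
            class = "scenario")
}

#' @export
#' @method print scenario
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %s\n", x$model,
              paste(sprintf("%s=%.3g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

compile_scenario <- function(model, p) {
  if (model %in% TWO_POP_MODELS) compile_two_pop(model, p)
  else compile_three_pop(model, p)
}

#' Expected joint spectrum of a scenario by coalescent Monte Carlo
#'
#' Simulates `n_reps` structured-coalescent genealogies per locus class
#' and accumulates each branch's length into the JAFS cell given by its
#' descendant-leaf counts per deme (branch-length weighting: mutations
#' arise at rate theta/2 per unit length, so entries are expected SNP
#' counts per unit theta).  Class spectra are combined by their genomic
#' weights and the orientation mixture is applied last.  With a fixed
#' seed the result is reproducible bit for bit.
#'
#' @param scenario A compiled `scenario`, or a model name (then `p` must
#'   be supplied).
#' @param sample_sizes Haploid sample sizes per deme.
#' @param n_reps Number of Monte-Carlo genealogies per locus class.
#' @param seed Optional integer seed (one independent stream per locus
#'   class is derived from it).
#' @param p Scenario parameters when `scenario` is a model name.
#' @return An unfolded `jafs` of expected SNP counts per unit theta.
#' @export
expected_jafs <- function(scenario, sample_sizes, n_reps = 10000,
                          seed = NULL, p = NULL) {
  if (is.character(scenario)) scenario <- compile_scenario(scenario, p)
  stopifnot(inherits(scenario, "scenario"))
  sample_sizes <- as.integer(sample_sizes)
  n_demes <- scenario$classes[[1]]$schedule$n_demes
  if (length(sample_sizes) != n_demes)
    abort(sprintf("scenario has %d demes; give one sample size per deme", n_demes))
  if (any(sample_sizes < 1)) abort("need at least one sampled chromosome per deme")
  if (n_reps < 1) abort("n_reps must be at least 1")
  acc <- NULL
  for (ci in seq_along(scenario$classes)) {
    cl <- scenario$classes[[ci]]
    if (cl$weight == 0) next
    if (!is.null(seed)) set.seed(seed + 97L * (ci - 1L))
    e <- cpp_expected_jafs(pack_schedule(cl$schedule), sample_sizes, as.integer(n_reps))
    acc <- if (is.null(acc)) cl$weight * e else acc + cl$weight * e
  }
  s <- new_jafs(acc, sample_sizes, folded = FALSE)
  if (scenario$O < 1) s <- misorient_jafs(s, scenario$O)
  s
}
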