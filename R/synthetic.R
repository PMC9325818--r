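# Synthetic activity datasets: valid, labeled, dated SMILES with planted
# activity motifs and temporal scaffold drift. Molecules are assembled from
# a fixed fragment library by template substitution, which guarantees
# chemical validity without a sanitization loop.

## scaffold templates, grouped into four structural families; every
## template carries an {A} slot, some a second {B} slot that is always
## filled when present. Substituents avoid sulfur and carboxyl/ester
## groups so the planted motifs never appear by accident.
.SCAFFOLDS <- list(
  phenyl = c("c1ccc({A})cc1", "c1ccc({A})c({B})c1",
             "c1ccc2cc({A})ccc2c1"),
  pyridyl = c("c1ccnc({A})c1", "c1cc({A})ccn1", "c1cnc({A})cn1"),
  piperazine = c("C1CN({A})CCN1{B}", "C1CCN({A})CC1", "C1CCC({A})NC1"),
  aliphatic = c("C1CCC({A})CC1", "CC(=O)NC({A})C", "CCNC(=O)C({A})({B})C")
)

## substituent pool. The thioether/sulfinyl entries are deliberate hard
## negatives for the default sulfonamide motif: with sulfur present in
## inactives too, no single atom-type fingerprint bit separates the
## classes and a model must learn the full S(=O)(=O)N environment.
.SUBSTITUENTS <- c("C", "CC", "SC", "CCC", "CC(C)C", "OC", "CSC", "OCC",
                   "CO", "CCO", "N(C)C", "CS(=O)C", "CN", "CCN(C)C",
                   "CCOC", "CCSC", "C(C)C", "CCC(C)C")

## linkers through which a motif may be attached to its slot; like the
## substituents these are generational (era-weighted under drift), so the
## motif's attachment environment itself evolves over time
.MOTIF_LINKERS <- c("", "C", "CC", "CCC", "OCC")

#' Specification for the synthetic dataset generator
#'
#' Collects the knobs that define a generated activity dataset: size,
#' planted activity motif, label noise, temporal scaffold drift, prevalence
#' and seed. Defaults emulate a mid-sized per-target bioactivity set: 600
#' molecules over a 10-year deposition span with moderate drift and 10%
#' label noise.
#'
#' @param n Number of molecules (default 600).
#' @param motif Activity motif as a fragment SMILES (default sulfonamide
#'   `"S(=O)(=O)N"`); actives carry it grafted at a random attachment point.
#' @param label_noise Probability in \[0, 0.5) of flipping a label.
#' @param drift Non-negative real controlling how strongly scaffold-family
#'   sampling weights shift across the date range (0 = stationary).
#' @param active_fraction Target prevalence of actives, in (0, 1).
#' @param seed Integer RNG seed.
#' @param date_start First deposition date (default `"2008-01-01"`).
#' @param date_span_days Span of deposition dates (default 3652, ten years).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n = 600L, motif = "S(=O)(=O)N", label_noise = 0.1,
                           drift = 1.0, active_fraction = 0.4, seed = 1L,
                           date_start = "2008-01-01",
                           date_span_days = 3652L) {
  stopifnot(n >= 1, label_noise >= 0, label_noise < 0.5, drift >= 0,
            active_fraction > 0, active_fraction < 1)
  motif_graph <- tryCatch(parse_smiles(motif),
                          error = function(e) stop("generator_spec: motif '",
                                                   motif, "' is unparsable"))
  structure(list(n = as.integer(n), motif = motif, motif_graph = motif_graph,
                 label_noise = label_noise, drift = drift,
                 active_fraction = active_fraction, seed = as.integer(seed),
                 date_start = as.Date(date_start),
                 date_span_days = as.integer(date_span_days)),
            class = "generator_spec")
}

## motif fragment SMILES -> substituent form usable inside a (...) branch;
## the attachment atom must come first
.motif_as_substituent <- function(motif) {
  switch(motif,
         "S(=O)(=O)N" = "S(N)(=O)=O",
         "C(=O)O"     = "C(=O)O",
         motif)
}

## sampling weights at date rank t in [0,1]: each fragment belongs to a
## "generation" centered at an era in [0, 1], and its weight decays as a
## Gaussian of the distance between t and that era (width shrinking with
## drift). Late-era fragments therefore barely exist in early (training)
## data — chemical novelty keeps growing through the late test window,
## the way new chemotypes enter real lead series. drift = 0 is uniform.
.drift_weights <- function(t, drift, k) {
  centers <- seq(0, 1, length.out = k)
  w <- exp(-drift * ((t - centers) / 0.3)^2)
  w / sum(w)
}

.assemble_molecule <- function(t, drift, motif_sub) {
  fam <- sample(seq_along(.SCAFFOLDS), 1,
                prob = .drift_weights(t, drift, length(.SCAFFOLDS)))
  tpl <- sample(.SCAFFOLDS[[fam]], 1)
  slots <- c("A", if (grepl("{B}", tpl, fixed = TRUE)) "B")
  fill <- stats::setNames(
    sample(.SUBSTITUENTS, length(slots), replace = TRUE,
           prob = .drift_weights(t, drift, length(.SUBSTITUENTS))),
    slots)
  if (!is.null(motif_sub)) {
    slot <- sample(slots, 1)
    linker <- sample(.MOTIF_LINKERS, 1,
                     prob = .drift_weights(t, drift, length(.MOTIF_LINKERS)))
    fill[slot] <- paste0(linker, motif_sub)
  }
  smi <- tpl
  for (s in names(fill)) {
    smi <- gsub(paste0("{", s, "}"), fill[[s]], smi, fixed = TRUE)
  }
  smi
}

#' Generate a labeled, dated synthetic activity dataset
#'
#' Molecules are assembled from a built-in fragment library (phenyl,
#' pyridyl, piperazine/piperidine, aliphatic templates with alkyl/ether/
#' amine substituents). Actives receive the motif grafted at a random
#' attachment point, optionally through a short alkyl linker; labels are
#' then flipped with probability `label_noise`. Deposition dates are drawn
#' uniformly over the configured span and the scaffold-family mixture
#' shifts along date rank at rate `drift`. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return A data.frame of class `activity_dataset` with columns `id`,
#'   `smiles`, `label` (0/1), `date` (`Date`) and `motif_planted`
#'   (construction bookkeeping: the motif SMILES, or `""`). The spec is
#'   attached as attribute `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  .generate(spec, motifs = spec$motif)
}

#' Generate a dataset whose actives split evenly between two motifs
#'
#' As [generate_dataset()], but actives alternate between `spec$motif` and
#' `motif_b`, so each active contains exactly one of the two motifs. The
#' two motifs are validated to be mutually non-substructures.
#'
#' @param spec A [generator_spec()].
#' @param motif_b Second motif fragment SMILES (default carboxylic acid
#'   `"C(=O)O"`).
#' @return An `activity_dataset` data.frame (see [generate_dataset()]).
#' @export
two_motif_dataset <- function(spec, motif_b = "C(=O)O") {
  stopifnot(inherits(spec, "generator_spec"))
  gb <- tryCatch(parse_smiles(motif_b),
                 error = function(e) stop("two_motif_dataset: motif '",
                                          motif_b, "' is unparsable"))
  if (has_motif(spec$motif_graph, gb) || has_motif(gb, spec$motif_graph)) {
    stop("two_motif_dataset: motifs must be mutually non-substructures")
  }
  .generate(spec, motifs = c(spec$motif, motif_b))
}

.generate <- function(spec, motifs) {
  set.seed(spec$seed)
  n <- spec$n
  u <- stats::runif(n)                  # date rank in [0,1]
  dates <- spec$date_start + floor(u * spec$date_span_days)
  active <- stats::rbinom(n, 1, spec$active_fraction)
  motif_of <- rep("", n)
  act_idx <- which(active == 1)
  if (length(act_idx) > 0) {
    ## actives split evenly (alternating) among the planted motifs
    motif_of[act_idx] <- motifs[((seq_along(act_idx) - 1) %% length(motifs)) + 1]
  }
  smiles <- character(n)
  for (k in seq_len(n)) {
    ms <- if (nzchar(motif_of[k])) .motif_as_substituent(motif_of[k]) else NULL
    smiles[k] <- .assemble_molecule(u[k], spec$drift, ms)
  }
  label <- active
  if (spec$label_noise > 0) {
    flip <- stats::rbinom(n, 1, spec$label_noise) == 1
    label[flip] <- 1 - label[flip]
  }
  ds <- data.frame(id = sprintf("SYN%05d", seq_len(n)), smiles = smiles,
                   label = as.integer(label), date = dates,
                   motif_planted = motif_of, stringsAsFactors = FALSE)
  attr(ds, "spec") <- spec
  class(ds) <- c("activity_dataset", class(ds))
  ds
}

#' Write a dataset as CSV plus a provenance JSON
#'
#' The CSV carries the standard columns (`id`, `smiles`, `label`, `date`,
#' ISO-8601 dates) plus any bookkeeping columns present; a sidecar
#' `<path>.provenance.json` records the generator settings and seed.
#'
#' @param dataset An `activity_dataset` (or compatible data.frame).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$date <- format(as.Date(df$date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  spec <- attr(dataset, "spec")
  if (!is.null(spec)) {
    prov <- spec[setdiff(names(spec), "motif_graph")]
    prov$date_start <- format(prov$date_start, "%Y-%m-%d")
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
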