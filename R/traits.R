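#' Classify reproductive frequency from the proportion of reproductive females
#'
#' A species in which half or fewer of the mature females are reproductive
#' during the breeding season is taken to reproduce on a biennial (or
#' longer) cycle; more than half indicates an annual cycle.
#'
#' @param rf proportion of reproductive mature females, in \[0, 1\].
#' @return `"annual"` or `"biennial"` (vectorised).
#' @examples
#' classify_frequency(c(0.5, 0.7))
#' @export
classify_frequency <- function(rf) {
  if (any(!is.finite(rf)) || any(rf < 0) || any(rf > 1)) {
    stop("'rf' must be a proportion in [0, 1]")
  }
  ifelse(rf > 0.5, "annual", "biennial")
}

#' Reproductive potential: value and category
#'
#' The expected number of offspring per female per year, estimated as mean
#' fecundity times reproductive frequency, and binned into low (< 5),
#' medium (5 to 10, closed interval so the rule is total) and high (> 10).
#'
#' @param mf mean fecundity (non-negative).
#' @param rf reproductive frequency as a proportion in \[0, 1\].
#' @return a data frame with columns `rp_value` and `rp_class`.
#' @examples
#' reproductive_potential(23, 0.7) # 16.1, high
#' @export
reproductive_potential <- function(mf, rf) {
  if (any(!is.finite(mf)) || any(mf < 0)) stop("'mf' must be non-negative")
  if (any(!is.finite(rf)) || any(rf < 0) || any(rf > 1)) {
    stop("'rf' must be a proportion in [0, 1]")
  }
  v <- mf * rf
  cls <- ifelse(v < 5, "low", ifelse(v <= 10, "medium", "high"))
  data.frame(rp_value = v, rp_class = cls)
}

#' Summarise specimen records into species-level reproductive traits
#'
#' Reproductive frequency is the proportion of mature females collected in
#' the reproductive season that carry vitellogenic follicles or oviductal
#' eggs; mean fecundity is the mean count of oviductal eggs plus embryos
#' over the females for which a count exists.
#'
#' @param records data frame of specimen records with columns
#'   `species_id`, `is_mature_female`, `is_reproductive`, `clutch_count`
#'   (NA allowed), `in_reproductive_season` (logical or 0/1).
#' @param species_id species to summarise; if `NULL`, all species present.
#' @return data frame with one row per species: `species_id`,
#'   `n_individuals` (mature females), `rf`, `freq_class`, `mf` (NA when
#'   no clutch was counted), `rp_value`, `rp_class` (NA when `mf` is NA).
#' @export
summarize_species <- function(records, species_id = NULL) {
  need <- c(
    "species_id", "is_mature_female", "is_reproductive",
    "clutch_count", "in_reproductive_season"
  )
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing specimen columns: ", paste(miss, collapse = ", "))
  if (any(!is.na(records$clutch_count) & !as.logical(records$is_reproductive))) {
    stop("a clutch count implies a reproductive female")
  }
  if (any(as.logical(records$is_reproductive) & !as.logical(records$is_mature_female))) {
    stop("a reproductive female must be mature")
  }
  ids <- if (is.null(species_id)) unique(records$species_id) else species_id
  one <- function(id) {
    r <- records[records$species_id == id & as.logical(records$is_mature_female), , drop = FALSE]
    season <- r[as.logical(r$in_reproductive_season), , drop = FALSE]
    if (nrow(season) == 0L) {
      stop("insufficient data: no mature females in the reproductive season for ", id)
    }
    rf <- mean(as.logical(season$is_reproductive))
    cc <- r$clutch_count[!is.na(r$clutch_count)]
    mf <- if (length(cc)) mean(cc) else NA_real_
    rp <- if (is.na(mf)) {
      data.frame(rp_value = NA_real_, rp_class = NA_character_)
    } else {
      reproductive_potential(mf, rf)
    }
    data.frame(
      species_id = id, n_individuals = nrow(r), rf = rf,
      freq_class = classify_frequency(rf), mf = mf,
      rp_value = rp$rp_value, rp_class = rp$rp_class
    )
  }
  out <- do.call(rbind, lapply(ids, one))
  rownames(out) <- NULL
  out
}

#' Read specimen records from CSV
#'
#' One row per specimen; boolean fields may be coded 0/1.
#'
#' @param path CSV file with the columns documented in [summarize_species()].
#' @return data frame of specimen records.
#' @export
read_specimen_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  for (b in c("is_mature_female", "is_reproductive", "in_reproductive_season")) {
    if (b %in% names(rec)) rec[[b]] <- as.logical(rec[[b]])
  }
  rec
}

# letter codes used in the species-trait CSV interchange format
.mode_codes <- c(O = "oviparous", V = "viviparous")
.rp_codes <- c(L = "low", M = "medium", H = "high")
.substrate_codes <- c(AQ = "aquatic", T = "terrestrial", A = "arboreal", F = "fossorial")
.habitat_codes <- c(Fo = "forest", W = "wetland", S = "savanna", G = "generalist")

#' Read a species-level trait table from CSV
#'
#' Expects the compact interchange format with columns
#' `species, tribe, N, RM, RF, RP, MF, SU, HU` and single-letter codes
#' (RM: O/V; RP: L/M/H; SU: AQ/T/A/F; HU: Fo/W/S/G; case-insensitive for
#' HU's "Fo").  The reproductive-potential value is recomputed as MF x RF
#' and the printed RP letter is kept alongside the rule-derived class;
#' rows where the two disagree are flagged in `rp_printed_mismatch`
#' rather than silently corrected.
#'
#' @param path CSV file.
#' @return data frame of species trait rows (one per species) with columns
#'   `species_id, tribe, n_individuals, mode, rf, freq_class, mf,
#'   rp_value, rp_class, rp_class_rule, rp_printed_mismatch, substrate,
#'   habitat`.  `rp_class` carries the printed category.
#' @export
read_species_traits <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "tribe", "N", "RM", "RF", "RP", "MF", "SU", "HU")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing trait columns: ", paste(miss, collapse = ", "))
  decode <- function(x, codes, what) {
    key <- match(toupper(x), toupper(names(codes)))
    if (anyNA(key)) {
      stop("unknown ", what, " code(s): ", paste(unique(x[is.na(key)]), collapse = ", "))
    }
    unname(codes[key])
  }
  rp <- reproductive_potential(tab$MF, tab$RF)
  printed <- decode(tab$RP, .rp_codes, "RP")
  data.frame(
    species_id = tab$species,
    tribe = tab$tribe,
    n_individuals = tab$N,
    mode = decode(tab$RM, .mode_codes, "RM"),
    rf = tab$RF,
    freq_class = classify_frequency(tab$RF),
    mf = tab$MF,
    rp_value = rp$rp_value,
    rp_class = printed,
    rp_class_rule = rp$rp_class,
    rp_printed_mismatch = printed != rp$rp_class,
    substrate = decode(tab$SU, .substrate_codes, "SU"),
    habitat = decode(tab$HU, .habitat_codes, "HU"),
    stringsAsFactors = FALSE
  )
}

check_traits_complete <- function(traits, fields) {
  for (f in fields) {
    bad <- which(is.na(traits[[f]]))
    if (length(bad)) {
      stop(
        "missing trait '", f, "' for species: ",
        paste(traits$species_id[bad], collapse = ", ")
      )
    }
  }
  invisible(traits)
}

#' Code the reproduction (response) matrix
#'
#' Builds the multivariate response for ordination from a species trait
#' table: mean fecundity as a numeric column, plus full dummy blocks for
#' reproductive mode (oviparous/viviparous), reproductive frequency
#' (annual/biennial - or the numeric proportion, see `frequency`) and
#' reproductive potential class (low/medium/high).  Columns are centred;
#' under `scaling = "correlation"` they are also standardised so that the
#' fecundity scale does not dominate the dummies, while
#' `scaling = "covariance"` leaves raw column variances in place
#' (a variance-covariance RDA).
#'
#' @param traits species trait table as returned by
#'   [read_species_traits()], [summarize_species()] (plus categories) or
#'   [snake_fixture()].
#' @param scaling `"covariance"` (centred only) or `"correlation"`
#'   (centred and standardised).
#' @param frequency code reproductive frequency as the `"binary"`
#'   annual/biennial dummies or as the `"numeric"` proportion `rf`.
#' @return a [coded_matrix()] with species ids as row names.
#' @examples
#' fx <- snake_fixture()
#' Y <- response_matrix(fx$traits, scaling = "covariance")
#' round(colMeans(Y), 12) # centred
#' @export
response_matrix <- function(traits,
                            scaling = c("covariance", "correlation"),
                            frequency = c("binary", "numeric")) {
  scaling <- match.arg(scaling)
  frequency <- match.arg(frequency)
  check_traits_complete(traits, c("species_id", "mode", "rf", "freq_class", "mf", "rp_class"))
  m <- cbind(
    MF = traits$mf,
    dummy_block(traits$mode, unname(.mode_codes)),
    if (frequency == "binary") {
      dummy_block(traits$freq_class, c("annual", "biennial"))
    } else {
      cbind(RF = traits$rf)
    },
    dummy_block(traits$rp_class, unname(.rp_codes))
  )
  colnames(m) <- sub("^(low|medium|high)$", "RP_\\1", colnames(m))
  rownames(m) <- traits$species_id
  coded_matrix(m,
    standardize = scaling == "correlation",
    coding = list(
      role = "response", scaling = scaling, frequency = frequency,
      numeric = "MF", dummies = setdiff(colnames(m), c("MF", "RF"))
    )
  )
}

#' Code the ecology (explanatory) matrix
#'
#' Full dummy blocks for the ecological classifications - by default
#' substrate use (aquatic, terrestrial, arboreal, fossorial) and habitat
#' use (forest, wetland, savanna, generalist).  Centred, never
#' standardised (0/1 indicators share a scale).
#'
#' @param traits species trait table (see [response_matrix()]).
#' @param vars which categorical columns of `traits` to code.
#' @return a [coded_matrix()] with one centred 0/1 column per category.
#' @export
ecology_matrix <- function(traits, vars = c("substrate", "habitat")) {
  check_traits_complete(traits, c("species_id", vars))
  known <- list(
    substrate = unname(.substrate_codes),
    habitat = unname(.habitat_codes)
  )
  blocks <- lapply(vars, function(v) {
    levs <- if (v %in% names(known)) {
      intersect(known[[v]], unique(traits[[v]]))
    } else {
      sort(unique(as.character(traits[[v]])))
    }
    dummy_block(traits[[v]], levs)
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- traits$species_id
  coded_matrix(m, standardize = FALSE, coding = list(role = "ecology", vars = vars))
}
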