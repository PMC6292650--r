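# Internal helpers: predictor-key conventions, dosage-table accessors,
# deterministic seed derivation.

# Residue predictor keys look like "HLA-DPB1@11:L" (position may be negative,
# never 0; residue is one of the 20 amino-acid letters or the gap "_").
# Classical-allele keys look like "HLA-DQA1*04:01".

residue_key <- function(gene, position, residue) {
  paste0(gene, "@", position, ":", residue)
}

allele_key <- function(gene, allele) {
  paste0(gene, "*", allele)
}

#' Parse residue predictor keys
#'
#' Splits keys of the form `gene@position:residue` (e.g. `"HLA-DPB1@11:L"`)
#' into their components.
#'
#' @param keys Character vector of residue keys.
#' @return A tibble with columns `key`, `gene`, `position` (integer, possibly
#'   negative) and `residue`.
#' @export
parse_residue_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+)@(-?[0-9]+):(.)$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    abort(paste0("malformed residue key(s): ", paste(keys[bad], collapse = ", ")))
  }
  tibble(
    key = keys,
    gene = vapply(m, `[[`, "", 2L),
    position = as.integer(vapply(m, `[[`, "", 3L)),
    residue = vapply(m, `[[`, "", 4L)
  )
}

#' Parse classical-allele predictor keys
#'
#' @param keys Character vector of keys of the form `gene*allele`
#'   (e.g. `"HLA-DQA1*04:01"`).
#' @return A tibble with columns `key`, `gene` and `allele`.
#' @export
parse_allele_key <- function(keys) {
  m <- regmatches(keys, regexec("^([^*]+)\\*(.+)$", keys))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("malformed allele key(s): ", paste(keys[bad], collapse = ", ")))
  }
  tibble(
    key = keys,
    gene = vapply(m, `[[`, "", 2L),
    allele = vapply(m, `[[`, "", 3L)
  )
}

# Columns of a dosage tibble other than the individual identifier.
dosage_cols <- function(d) setdiff(names(d), "individual_id")

# Numeric matrix view of a dosage tibble (rows named by individual).
dosage_matrix <- function(d) {
  cols <- dosage_cols(d)
  m <- as.matrix(d[cols])
  rownames(m) <- d$individual_id
  storage.mode(m) <- "double"
  m
}

as_dosage_tibble <- function(m, individual_id = rownames(m)) {
  out <- as_tibble(m)
  tibble(individual_id = individual_id) |> dplyr::bind_cols(out)
}

# Deterministic per-stage seed stream: stable string hash folded into the
# master seed, kept inside the 32-bit integer range R requires.
derive_seed <- function(master, stage) {
  codes <- utf8ToInt(as.character(stage))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(paste0(
      "`", name, "` must be in ", if (lo_open) "(" else "[", lo, ", ", hi,
      if (hi_open) ")" else "]"
    ))
  }
  as.numeric(x)
}

check_phenotype <- function(phenotype, n = NULL) {
  y <- as.numeric(phenotype)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort("`phenotype` must be binary 0/1 with no missing values")
  }
  if (length(unique(y)) < 2L) {
    abort("`phenotype` must contain both cases and controls")
  }
  if (!is.null(n) && length(y) != n) {
    abort("`phenotype` length does not match the dosage table")
  }
  y
}

# Intercept-plus-covariates design matrix (Z may be NULL).
intercept_design <- function(n, Z) {
  cbind(`(Intercept)` = rep(1, n), Z)
}

# Align an optional covariate data frame into a numeric matrix (or NULL).
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cv <- as.data.frame(covariates)
  cv$individual_id <- NULL
  if (nrow(cv) != n) abort("`covariates` rows do not match the phenotype length")
  m <- as.matrix(cv)
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) abort("covariates must be finite")
  const <- apply(m, 2L, function(x) var(x) == 0)
  if (any(const)) {
    abort(paste0("constant covariate column(s): ",
                 paste(colnames(m)[const], collapse = ", ")))
  }
  m
}
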