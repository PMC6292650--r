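# TSV dialects. All tables are written with "#"-prefixed metadata header
# lines (parameter echo) so outputs are self-describing; readers skip them.

write_tsv_commented <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(paste0("# ", nm, ": ", paste(format(meta[[nm]]), collapse = " ")),
               con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", comment.char = "#",
                              stringsAsFactors = FALSE,
                              check.names = FALSE))
}

#' Write / read a genotype posterior table
#'
#' One row per candidate genotype: `individual_id`, `gene`, `allele1`,
#' `allele2`, `posterior`.
#'
#' @param posteriors Posterior tibble.
#' @param path File path.
#' @param meta Named list echoed as `# key: value` header lines.
#' @return `path` (write) or the tibble (read).
#' @export
write_posteriors <- function(posteriors, path, meta = list()) {
  write_tsv_commented(posteriors, path, meta)
}

#' @rdname write_posteriors
#' @export
read_posteriors <- function(path) {
  out <- read_tsv_commented(path)
  out$allele1 <- as.character(out$allele1)
  out$allele2 <- as.character(out$allele2)
  out
}

#' Write / read a peptide alignment table
#'
#' Columns `gene`, `allele`, `position` (integer, possibly negative, never
#' 0), `residue` (single character, `"_"` = absent).
#'
#' @inheritParams write_posteriors
#' @param alignment Alignment tibble.
#' @return `path` (write) or the tibble (read).
#' @export
write_alignment <- function(alignment, path, meta = list()) {
  write_tsv_commented(alignment, path, meta)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  out <- read_tsv_commented(path)
  out$allele <- as.character(out$allele)
  out$residue <- as.character(out$residue)
  out$position <- as.integer(out$position)
  out
}

#' Write / read a phenotype table
#'
#' Columns `individual_id`, `status` (0/1), plus optional covariates.
#'
#' @inheritParams write_posteriors
#' @param phenotypes Phenotype tibble.
#' @return `path` (write) or the tibble (read).
#' @export
write_phenotypes <- function(phenotypes, path, meta = list()) {
  write_tsv_commented(phenotypes, path, meta)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) read_tsv_commented(path)

#' Write / read a dosage matrix
#'
#' Individuals by predictors; header row carries the predictor keys
#' (`gene@position:residue` for residues, `gene*allele` for classical
#' alleles).
#'
#' @inheritParams write_posteriors
#' @param dosages Dosage tibble.
#' @return `path` (write) or the tibble (read).
#' @export
write_dosage <- function(dosages, path, meta = list()) {
  write_tsv_commented(dosages, path, meta)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) read_tsv_commented(path)

#' Validate pipeline input files
#'
#' Schema, invariant and cross-file consistency checks over the TSV inputs:
#' per individual-gene posterior sums (1 within 1e-6), posterior range,
#' the position-0 ban, residue alphabet, per-gene position coverage, binary
#' phenotype, and posterior alleles resolvable in the alignment. Fails
#' soft: every violation becomes one report row.
#'
#' @param posterior_path,alignment_path Paths to the posterior and
#'   alignment TSVs.
#' @param phenotype_path Optional phenotype TSV path.
#' @return A tibble `file`, `rule`, `detail`; zero rows when clean.
#' @export
validate_inputs <- function(posterior_path, alignment_path,
                            phenotype_path = NULL) {
  for (p in c(posterior_path, alignment_path, phenotype_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  issues <- list()
  note <- function(file, rule, detail) {
    issues[[length(issues) + 1L]] <<- tibble(file = file, rule = rule,
                                             detail = detail)
  }

  post <- read_posteriors(posterior_path)
  need <- c("individual_id", "gene", "allele1", "allele2", "posterior")
  if (!all(need %in% names(post))) {
    note(posterior_path, "schema",
         paste0("missing column(s): ", paste(setdiff(need, names(post)),
                                             collapse = ", ")))
  } else {
    bad_range <- post$posterior < 0 | post$posterior > 1
    if (any(bad_range)) {
      note(posterior_path, "posterior-range",
           paste0(sum(bad_range), " posterior(s) outside [0, 1]"))
    }
    sums <- post |>
      group_by(.data$individual_id, .data$gene) |>
      summarise(total = sum(.data$posterior), .groups = "drop") |>
      filter(abs(.data$total - 1) > 1e-6)
    for (i in seq_len(nrow(sums))) {
      note(posterior_path, "posterior-sum",
           paste0("individual ", sums$individual_id[i], ", gene ",
                  sums$gene[i], ": posteriors sum to ",
                  format(sums$total[i], digits = 7)))
    }
  }

  aln <- read_alignment(alignment_path)
  need <- c("gene", "allele", "position", "residue")
  if (!all(need %in% names(aln))) {
    note(alignment_path, "schema",
         paste0("missing column(s): ", paste(setdiff(need, names(aln)),
                                             collapse = ", ")))
  } else {
    if (any(aln$position == 0L, na.rm = TRUE)) {
      note(alignment_path, "position-zero",
           "position 0 is disallowed (leader positions are negative)")
    }
    bad_res <- !aln$residue %in% c(AA_LETTERS, "_")
    if (any(bad_res)) {
      note(alignment_path, "residue-alphabet",
           paste0("invalid residue(s): ",
                  paste(unique(aln$residue[bad_res]), collapse = ", ")))
    }
    cover <- aln |>
      group_by(.data$gene, .data$allele) |>
      summarise(sig = paste(sort(unique(.data$position)), collapse = ","),
                .groups = "drop") |>
      group_by(.data$gene) |>
      summarise(n_sig = dplyr::n_distinct(.data$sig), .groups = "drop") |>
      filter(.data$n_sig > 1L)
    for (g in cover$gene) {
      note(alignment_path, "position-coverage",
           paste0("gene ", g, ": alleles do not cover the same position set"))
    }
    if (all(c("individual_id", "gene") %in% names(post))) {
      post_alleles <- unique(c(paste(post$gene, post$allele1),
                               paste(post$gene, post$allele2)))
      aln_alleles <- unique(paste(aln$gene, aln$allele))
      orphan <- setdiff(post_alleles, aln_alleles)
      if (length(orphan) > 0L) {
        note(posterior_path, "allele-unresolvable",
             paste0(length(orphan), " posterior allele(s) absent from the ",
                    "alignment, e.g. ", orphan[1L]))
      }
    }
  }

  if (!is.null(phenotype_path)) {
    ph <- read_phenotypes(phenotype_path)
    if (!all(c("individual_id", "status") %in% names(ph))) {
      note(phenotype_path, "schema", "need columns individual_id, status")
    } else if (!all(ph$status %in% c(0L, 1L))) {
      note(phenotype_path, "status-binary", "status must be 0/1")
    }
  }

  if (length(issues) == 0L) {
    tibble(file = character(), rule = character(), detail = character())
  } else {
    bind_rows(issues)
  }
}
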