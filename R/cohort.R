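CALL_COLUMNS <- c("A_1", "A_2", "B_1", "B_2", "C_1", "C_2",
                  "DRB1_1", "DRB1_2")
DRUGS <- c("CBZ", "LTG", "OXC")

locus_columns <- function(locus) paste0(locus, c("_1", "_2"))

#' Construct a genotype cohort
#'
#' A cohort is a set of genotyped individuals, each labelled case (developed
#' the drug reaction) or control (drug-tolerant), with two allele calls per
#' locus. A locus may be entirely missing for an individual (insufficient
#' DNA); a half-typed locus is rejected.
#'
#' @param records A data frame with columns \code{sample_id}, \code{group}
#'   (\code{"case"}/\code{"control"}) and the eight call columns
#'   \code{A_1, A_2, B_1, B_2, C_1, C_2, DRB1_1, DRB1_2} holding allele names
#'   or \code{NA}.
#' @param drug Drug label for the cohort: \code{"CBZ"}, \code{"LTG"},
#'   \code{"OXC"}, or \code{"pooled"}.
#' @return An object of class \code{hla_cohort}.
#' @export
hla_cohort <- function(records, drug = "pooled") {
  stopifnot(is.data.frame(records))
  required <- c("sample_id", "group", CALL_COLUMNS)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("cohort records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$sample_id <- as.character(records$sample_id)
  records$group <- as.character(records$group)
  bad_group <- !records$group %in% c("case", "control")
  if (any(bad_group)) {
    stop("invalid group value(s): ",
         paste(unique(records$group[bad_group]), collapse = ", "),
         call. = FALSE)
  }
  dup <- records$sample_id[duplicated(records$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (locus in HLA_LOCI) {
    cols <- locus_columns(locus)
    c1 <- records[[cols[1L]]]
    c2 <- records[[cols[2L]]]
    c1[!is.na(c1) & !nzchar(trimws(c1))] <- NA
    c2[!is.na(c2) & !nzchar(trimws(c2))] <- NA
    half <- xor(is.na(c1), is.na(c2))
    if (any(half)) {
      stop("half-missing genotype at locus ", locus, " on row(s) ",
           paste(which(half), collapse = ", "), call. = FALSE)
    }
    # normalise via the unique values: cohorts hold few distinct alleles
    norm <- function(v) {
      out <- rep(NA_character_, length(v))
      ok <- !is.na(v)
      if (!any(ok)) return(out)
      uu <- unique(v[ok])
      mapped <- vapply(uu, function(u) {
        tryCatch(canonical_allele(u, locus = locus),
          error = function(e) {
            stop("row ", which(ok & v == u)[1L], ", locus ", locus, ": ",
                 conditionMessage(e), call. = FALSE)
          })
      }, character(1L))
      out[ok] <- mapped[match(v[ok], uu)]
      out
    }
    records[[cols[1L]]] <- norm(c1)
    records[[cols[2L]]] <- norm(c2)
  }
  rownames(records) <- NULL
  structure(list(drug = as.character(drug), records = records),
            class = "hla_cohort")
}

#' @export
print.hla_cohort <- function(x, ...) {
  tab <- table(factor(x$records$group, levels = c("case", "control")))
  cat(sprintf("HLA cohort [%s]: %d cases, %d controls\n",
              x$drug, tab[["case"]], tab[["control"]]))
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort An [hla_cohort()].
#' @return Integer count.
#' @export
cohort_size <- function(cohort) nrow(cohort$records)

#' Read a genotype cohort from a delimited text file
#'
#' Expects a CSV or TSV (detected from the header line) with columns
#' \code{sample_id, group, drug, A_1, A_2, B_1, B_2, C_1, C_2, DRB1_1,
#' DRB1_2}; the \code{drug} column is optional when \code{drug} is supplied.
#' Empty strings are missing calls. Allele names are normalised to the
#' canonical \code{HLA-<locus>*XX:XX} rendering.
#'
#' @param path Path to the file.
#' @param drug Drug label; defaults to the file's \code{drug} column (which
#'   must then be constant).
#' @return An [hla_cohort()].
#' @export
read_cohort <- function(path, drug = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = "",
                          check.names = FALSE, quote = "\"",
                          comment.char = "")
  if (is.null(drug)) {
    if (!"drug" %in% names(df)) {
      stop("no drug column in ", path, " and no drug argument given",
           call. = FALSE)
    }
    drugs <- unique(df$drug)
    if (length(drugs) != 1L) {
      stop("file mixes drugs (", paste(drugs, collapse = ", "),
           "); pass cohorts separately and pool explicitly", call. = FALSE)
    }
    drug <- drugs
  }
  hla_cohort(df, drug = drug)
}

#' Write a cohort in the package's genotype file format
#'
#' @param cohort An [hla_cohort()].
#' @param path Output path; comma-separated, empty string for missing calls.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$records
  df <- cbind(df[, c("sample_id", "group")],
              drug = cohort$drug,
              df[, CALL_COLUMNS])
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Carrier status of each individual for one allele
#'
#' An individual carries an allele if at least one of the two calls at the
#' allele's locus equals it; homozygotes count once. Individuals untyped at
#' that locus are \code{"unknown"}.
#'
#' @param cohort An [hla_cohort()].
#' @param allele An [hla_allele()] or allele name.
#' @return Character vector over records: \code{"carrier"},
#'   \code{"non-carrier"} or \code{"unknown"}.
#' @export
carrier_status <- function(cohort, allele) {
  allele <- parse_allele(allele)
  target <- format(allele)
  cols <- locus_columns(allele$locus)
  c1 <- cohort$records[[cols[1L]]]
  c2 <- cohort$records[[cols[2L]]]
  out <- ifelse(is.na(c1), "unknown",
                ifelse(c1 == target | c2 == target, "carrier",
                       "non-carrier"))
  out
}

#' Carrier status of a single genotype record
#'
#' @param record One row of a cohort's \code{records} data frame (or a list
#'   with the call columns).
#' @param allele An [hla_allele()] or allele name.
#' @return \code{"carrier"}, \code{"non-carrier"} or \code{"unknown"}.
#' @export
is_carrier <- function(record, allele) {
  allele <- parse_allele(allele)
  cols <- locus_columns(allele$locus)
  c1 <- record[[cols[1L]]]
  c2 <- record[[cols[2L]]]
  if (is.na(c1) || is.na(c2)) return("unknown")
  target <- format(allele)
  if (c1 == target || c2 == target) "carrier" else "non-carrier"
}

#' Build the 2x2 carrier table for one allele
#'
#' Denominators count only individuals typed at the allele's locus, so they
#' shrink per locus rather than dropping whole records.
#'
#' @param cohort An [hla_cohort()].
#' @param allele An [hla_allele()] or allele name.
#' @return A [carrier_table()].
#' @examples
#' \dontrun{build_carrier_table(cohort, "HLA-DRB1*04:06")}
#' @export
build_carrier_table <- function(cohort, allele) {
  status <- carrier_status(cohort, allele)
  grp <- cohort$records$group
  known <- status != "unknown"
  n_case <- sum(known & grp == "case")
  n_ctrl <- sum(known & grp == "control")
  if (n_case == 0L || n_ctrl == 0L) {
    stop("no usable individuals in the ",
         if (n_case == 0L) "case" else "control",
         " arm at locus ", parse_allele(allele)$locus, call. = FALSE)
  }
  carrier_table(sum(status == "carrier" & grp == "case"), n_case,
                sum(status == "carrier" & grp == "control"), n_ctrl)
}

#' Enumerate the distinct alleles observed at a locus
#'
#' Returns every distinct two-field allele observed at the locus across
#' cases and controls together, with its pooled carrier count (homozygotes
#' counted once), sorted by descending carrier count and then by name. The
#' number of rows is the multiplicity used for per-locus Bonferroni
#' correction.
#'
#' @param cohort An [hla_cohort()].
#' @param locus One of \code{"A"}, \code{"B"}, \code{"C"}, \code{"DRB1"}.
#' @return Data frame with columns \code{allele} (canonical name) and
#'   \code{carriers}.
#' @export
enumerate_alleles <- function(cohort, locus) {
  locus <- match.arg(locus, HLA_LOCI)
  cols <- locus_columns(locus)
  c1 <- cohort$records[[cols[1L]]]
  c2 <- cohort$records[[cols[2L]]]
  keep <- !is.na(c1)
  if (!any(keep)) {
    return(data.frame(allele = character(0), carriers = integer(0)))
  }
  # carrier = at least one copy; homozygotes once
  per_ind <- mapply(function(x, y) unique(c(x, y)),
                    c1[keep], c2[keep], SIMPLIFY = FALSE)
  counts <- table(unlist(per_ind, use.names = FALSE))
  out <- data.frame(allele = names(counts),
                    carriers = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$carriers, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool cohorts, counting shared individuals once
#'
#' Individuals appearing in more than one cohort (e.g. tolerant to two
#' drugs) are de-duplicated by \code{sample_id}. Shared ids must carry
#' identical genotypes. An individual who is a case in one cohort and a
#' control in another is kept as a case, and the conflict is reported via
#' \code{message()}.
#'
#' @param cohorts A list of [hla_cohort()] objects.
#' @param drug Label for the pooled cohort.
#' @return An [hla_cohort()].
#' @export
pool_cohorts <- function(cohorts, drug = "pooled") {
  stopifnot(length(cohorts) >= 1L)
  if (inherits(cohorts, "hla_cohort")) cohorts <- list(cohorts)
  all_rec <- do.call(rbind, lapply(cohorts, function(x) x$records))
  ids <- unique(all_rec$sample_id)
  keep <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- all_rec[all_rec$sample_id == ids[i], , drop = FALSE]
    if (nrow(rows) > 1L) {
      geno <- rows[, CALL_COLUMNS, drop = FALSE]
      same <- vapply(seq_len(nrow(geno)), function(j) {
        identical(unname(unlist(geno[j, ])), unname(unlist(geno[1L, ])))
      }, logical(1L))
      if (!all(same)) {
        stop("conflicting genotypes for sample_id ", ids[i], call. = FALSE)
      }
      groups <- unique(rows$group)
      if (length(groups) > 1L) {
        message("sample ", ids[i],
                " is a case for one drug and control for another; ",
                "kept as case in the pooled cohort")
        rows <- rows[rows$group == "case", , drop = FALSE]
      }
    }
    keep[[i]] <- rows[1L, , drop = FALSE]
  }
  hla_cohort(do.call(rbind, keep), drug = drug)
}
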