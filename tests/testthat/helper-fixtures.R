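# Fixture builders: cohorts constructed record-by-record to reproduce exact
# published carrier counts, plus small writers for file-based tests.

filler_allele <- function(locus) {
  c(A = "HLA-A*11:01", B = "HLA-B*46:01", C = "HLA-C*01:02",
    DRB1 = "HLA-DRB1*09:01")[[locus]]
}

empty_records <- function(n, group) {
  df <- data.frame(sample_id = sprintf("%s%04d", substr(group, 1, 2),
                                       seq_len(n)),
                   group = group, stringsAsFactors = FALSE)
  for (locus in hlarisk::HLA_LOCI) {
    fill <- filler_allele(locus)
    df[[paste0(locus, "_1")]] <- fill
    df[[paste0(locus, "_2")]] <- fill
  }
  df
}

# Cohort where `allele` has exactly a/n_case case carriers and c/n_ctrl
# control carriers (heterozygous against the locus filler); other loci are
# constant filler. n_case_missing/n_ctrl_missing extra individuals are
# untyped at the allele's locus.
make_count_cohort <- function(allele, a, n_case, c, n_ctrl,
                              n_case_missing = 0, n_ctrl_missing = 0,
                              drug = "OXC") {
  al <- hlarisk::parse_allele(allele)
  col1 <- paste0(al$locus, "_1")
  col2 <- paste0(al$locus, "_2")
  cases <- empty_records(n_case + n_case_missing, "case")
  ctrls <- empty_records(n_ctrl + n_ctrl_missing, "control")
  ctrls$sample_id <- paste0("ct", ctrls$sample_id)
  if (a > 0) cases[[col1]][seq_len(a)] <- format(al)
  if (c > 0) ctrls[[col1]][seq_len(c)] <- format(al)
  if (n_case_missing > 0) {
    idx <- n_case + seq_len(n_case_missing)
    cases[[col1]][idx] <- NA
    cases[[col2]][idx] <- NA
  }
  if (n_ctrl_missing > 0) {
    idx <- n_ctrl + seq_len(n_ctrl_missing)
    ctrls[[col1]][idx] <- NA
    ctrls[[col2]][idx] <- NA
  }
  hlarisk::hla_cohort(rbind(cases, ctrls), drug = drug)
}

# Cohort reproducing the published CBZ cross-classification of A*24:02 and
# B*38:02: joint strata (pp, pn, np, nn) of 5/26/13/96 cases and
# 1/27/9/140 controls among the both-typed, plus 5 cases and 2 controls
# typed at B only (B non-carriers, A untyped).
make_cbz_cohort <- function() {
  a24 <- "HLA-A*24:02"
  b38 <- "HLA-B*38:02"
  build_arm <- function(strata, n_b_only, group, prefix) {
    n <- sum(strata) + n_b_only
    df <- empty_records(n, group)
    df$sample_id <- paste0(prefix, df$sample_id)
    carrier_a <- rep(c(TRUE, TRUE, FALSE, FALSE, FALSE),
                     c(strata, n_b_only))
    carrier_b <- rep(c(TRUE, FALSE, TRUE, FALSE, FALSE),
                     c(strata, n_b_only))
    a_missing <- rep(c(FALSE, FALSE, FALSE, FALSE, TRUE),
                     c(strata, n_b_only))
    df$A_1[carrier_a] <- a24
    df$B_1[carrier_b] <- b38
    df$A_1[a_missing] <- NA
    df$A_2[a_missing] <- NA
    df
  }
  hlarisk::hla_cohort(
    rbind(build_arm(c(5, 26, 13, 96), 5, "case", "x"),
          build_arm(c(1, 27, 9, 140), 2, "control", "y")),
    drug = "CBZ"
  )
}

write_tmp_cohort_file <- function(records, path = withr::local_tempfile(
                                    fileext = ".csv",
                                    .local_envir = parent.frame()),
                                  drug = "OXC") {
  df <- cbind(records[, c("sample_id", "group")], drug = drug,
              records[, paste0(rep(hlarisk::HLA_LOCI, each = 2),
                               c("_1", "_2"))])
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  path
}

# The published per-drug and pooled carrier-count tables (inputs to the
# pipeline, used throughout the tests).
published_tables <- function() {
  list(
    drb1_oxc  = hlarisk::carrier_table(8, 51, 1, 94),
    b3802_cbz = hlarisk::carrier_table(18, 145, 10, 179),
    comb_cbz  = hlarisk::carrier_table(44, 140, 37, 177),
    a2402_pool = hlarisk::carrier_table(56, 253, 48, 308),
    a3001_pool = hlarisk::carrier_table(14, 253, 7, 308),
    b3501_pool = hlarisk::carrier_table(11, 261, 4, 344),
    b3802_pool = hlarisk::carrier_table(28, 261, 20, 344),
    drb1_pool  = hlarisk::carrier_table(17, 259, 9, 343)
  )
}
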