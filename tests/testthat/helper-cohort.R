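# Fixture builders shared across test files. All fixtures are built in
# code; no binary data.

# small hand-written cohort with complete biometry
make_test_cohort <- function(n = 5, gat = NULL, dct = NULL, cct = NULL,
                             r = NULL, age = NULL, label = "test") {
  if (is.null(gat)) gat <- seq(12, 20, length.out = n)
  if (is.null(dct)) dct <- gat + 2
  if (is.null(cct)) cct <- seq(520, 580, length.out = n)
  if (is.null(r)) r <- seq(7.5, 8.1, length.out = n)
  if (is.null(age)) age <- seq(25, 65, length.out = n)
  iop_cohort(data.frame(
    subject_id = paste0("S", seq_len(n)),
    age = age, cct_um = cct, r_mm = r,
    iop_gat = gat, iop_dct = dct,
    stringsAsFactors = FALSE
  ), label = label)
}

# write a cohort data.frame (possibly malformed) to a temp CSV
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
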