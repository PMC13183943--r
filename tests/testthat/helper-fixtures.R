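# Shared fixtures built in code.

# an error-free read pair from one insert of the given design
make_clean_pair <- function(insert, design, q = 35L) {
  L <- design$read_len
  list(seq1 = substr(insert, 1L, L),
       qual1 = rep(q, L),
       seq2 = climkit:::.revcomp(substr(insert, nchar(insert) - L + 1L,
                                        nchar(insert))),
       qual2 = rep(q, L))
}

# reporter with substitutions applied: subs is a named list codon_idx -> codon
mutate_reporter <- function(design, subs) {
  r <- design$wt_reporter
  for (i in seq_along(subs)) {
    ci <- as.integer(names(subs)[i])
    substr(r, 3L * ci - 2L, 3L * ci) <- subs[[i]]
  }
  r
}

insert_from_reporter <- function(design, reporter,
                                 hex = c("ACGTCA", "TTGACG")) {
  paste0(hex[1], design$anchor5, reporter, design$anchor3, hex[2])
}

gz_lines <- function(path) readLines(gzfile(path))

expect_tvd_small <- function(a, b, tol) {
  expect_lt(sum(abs(a / sum(a) - b / sum(b))) / 2, tol)
}
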