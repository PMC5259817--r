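#' Generate a synthetic reference protein database
#'
#' Random protein records over the 20 standard amino acids (uniform
#' composition) whose lengths sum exactly to `total_aa`. Used to stand in for
#' a reference proteome when only database-size arithmetic matters, e.g. when
#' reproducing the total length of simulated proteogenomic databases built
#' from a reference of a stated size.
#'
#' @param total_aa Total residue count of the database.
#' @param n_proteins Number of records (lengths as equal as possible).
#' @param seed Integer seed.
#' @return A sequence-database tibble with `provenance = "reference"`.
#' @export
#' @examples
#' total_aa(synthetic_reference_db(1000, n_proteins = 10))
synthetic_reference_db <- function(total_aa, n_proteins = 1000L, seed = 1L) {
  assert_count(total_aa, "total_aa", min = 1L)
  assert_count(n_proteins, "n_proteins", min = 1L)
  if (n_proteins > total_aa) abort("`n_proteins` must be <= `total_aa`")
  len <- rep(total_aa %/% n_proteins, n_proteins)
  extra <- total_aa %% n_proteins
  if (extra > 0L) len[seq_len(extra)] <- len[seq_len(extra)] + 1L
  withr::with_seed(substream_seed(seed, "synthetic_reference"), {
    chars <- sample(AA_STANDARD, total_aa, replace = TRUE)
    ends <- cumsum(len)
    starts <- ends - len + 1L
    seqs <- vapply(seq_len(n_proteins), function(i) {
      paste(chars[starts[i]:ends[i]], collapse = "")
    }, character(1))
    seq_db(sprintf("synt_prot_%06d", seq_len(n_proteins)), seqs,
           provenance = "reference", source_tag = "synthetic")
  })
}
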