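# Longest run of consecutive, non-overlapping copies of `unit` in `s`.
longest_unit_run <- function(s, unit) {
  if (nchar(s) < nchar(unit)) return(0L)
  m <- gregexpr(sprintf("(?:%s)+", unit), s)[[1]]
  if (m[1] == -1) return(0L)
  max(attr(m, "match.length")) %/% nchar(unit)
}

#' Call telomeric repeat arrays at scaffold ends
#'
#' Scans a window at each scaffold terminus for consecutive copies of the
#' telomere repeat unit. Chromosome ends carry the G-rich strand reading
#' towards the terminus, so at the 3' (right) end the forward unit
#' (`TTAGGG` by default) is expected, and at the 5' (left) end its reverse
#' complement (`CCCTAA`). An end is called telomeric when the longest
#' consecutive run in its window reaches `min_copies` units; a single
#' interruption breaks a run.
#'
#' @param genome A genome tibble ([read_genome_fasta()]) or named character
#'   vector of sequences.
#' @param unit Telomere repeat unit on the forward/G-rich strand (default
#'   `"TTAGGG"`, the common fungal repeat).
#' @param min_copies Minimum consecutive copies to call an end (default 5).
#' @param window Number of terminal bases searched at each end (default 200);
#'   truncated, with a warning, for scaffolds shorter than the window.
#' @return A tibble with one row per scaffold: `scaffold_id`, `end5`,
#'   `copies5`, `end3`, `copies3`, `class` (`complete`, `one_end`, `none`).
#' @export
find_telomeres <- function(genome, unit = "TTAGGG", min_copies = 5,
                           window = 200) {
  assert_dna_motif(unit, "unit")
  if (window < nchar(unit) * min_copies) {
    abort("window must hold at least min_copies units")
  }
  if (!is.data.frame(genome)) {
    genome <- tibble(scaffold_id = names(genome),
                     sequence = unname(unlist(genome)))
  }
  unit5 <- revcomp(unit)
  res <- purrr::map2(genome$scaffold_id, genome$sequence, function(id, s) {
    n <- nchar(s)
    w <- window
    if (n < window) {
      warn(sprintf("scaffold %s (%d bp) shorter than window; truncated", id, n))
      w <- n
    }
    copies5 <- longest_unit_run(substr(s, 1L, w), unit5)
    copies3 <- longest_unit_run(substr(s, n - w + 1L, n), unit)
    tibble(scaffold_id = id,
           end5 = copies5 >= min_copies, copies5 = copies5,
           end3 = copies3 >= min_copies, copies3 = copies3)
  })
  calls <- dplyr::bind_rows(res)
  calls$class <- dplyr::case_when(
    calls$end5 & calls$end3 ~ "complete",
    calls$end5 | calls$end3 ~ "one_end",
    TRUE ~ "none"
  )
  calls
}

#' Summarise telomere calls across an assembly
#'
#' Partitions scaffolds into those with telomeric repeats at both ends
#' (candidate complete chromosomes), one end, or neither.
#'
#' @param calls A tibble from [find_telomeres()], one row per scaffold.
#' @return A one-row tibble with integer columns `complete`, `one_end`,
#'   `none`.
#' @export
telomere_summary <- function(calls) {
  if (anyDuplicated(calls$scaffold_id)) {
    abort("duplicate scaffold_id in telomere calls")
  }
  tibble(
    complete = sum(calls$end5 & calls$end3),
    one_end = sum(xor(calls$end5, calls$end3)),
    none = sum(!calls$end5 & !calls$end3)
  )
}
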