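#' Read a labelled reference protein database
#'
#' The reference database emulates a taxonomy-annotated protein collection:
#' a FASTA of protein sequences plus a tab-separated taxonomy map with
#' columns `id`, `kingdom`, `phylum`, `family`, `species`, `is_viral`,
#' `is_rdrp`.  Every `is_rdrp` protein must also be `is_viral`.
#'
#' @param fasta path to the protein FASTA.
#' @param taxonomy_tsv path to the taxonomy map.
#' @return data.frame with one row per protein: `id`, `seq` and the
#'   taxonomy columns.
#' @export
read_reference_db <- function(fasta, taxonomy_tsv) {
  seqs <- read_fasta(fasta)
  tax <- utils::read.delim(taxonomy_tsv, stringsAsFactors = FALSE,
                           colClasses = list(id = "character"))
  need <- c("id", "kingdom", "phylum", "family", "species",
            "is_viral", "is_rdrp")
  if (!all(need %in% names(tax)))
    stop("taxonomy map missing columns: ",
         paste(setdiff(need, names(tax)), collapse = ", "))
  tax$is_viral <- as.logical(tax$is_viral)
  tax$is_rdrp <- as.logical(tax$is_rdrp)
  if (!all(tax$id %in% names(seqs)))
    stop("taxonomy map lists proteins absent from the FASTA")
  tax$seq <- unname(seqs[tax$id])
  validate_reference_db(tax)
  tax[, c("id", "seq", need[-1])]
}

validate_reference_db <- function(db) {
  stopifnot(is.data.frame(db), nrow(db) > 0,
            !anyDuplicated(db$id),
            all(db$is_viral[db$is_rdrp]))
  invisible(db)
}

#' Write a reference database to FASTA plus taxonomy TSV
#'
#' @param db reference database data.frame (see [read_reference_db()]).
#' @param dir output directory; files `proteins.fasta` and `taxonomy.tsv`
#'   are created inside it.
#' @return the directory, invisibly.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(setNames(db$seq, db$id), file.path(dir, "proteins.fasta"))
  tax <- db[, c("id", "kingdom", "phylum", "family", "species",
                "is_viral", "is_rdrp")]
  utils::write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
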