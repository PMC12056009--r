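#' @keywords internal
#' @importFrom data.table data.table as.data.table rbindlist setnames
#'   setcolorder setorder setattr copy fread fwrite CJ %chin% .N .SD :=
#' @importFrom stats setNames
"_PACKAGE"

.datatable.aware <- TRUE

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".BY", "transcript_id", "read_length", "site", "cds_start",
  "cds_end", "five_prime_pos", "tri_start", "n_gene", "codon", "count",
  "n_reads", "expected", "observed", "occupancy", "o_t", "o_c", "value",
  "mean_signal", "z", "p", "p_bh", "flagged_increase", "log2_ratio",
  "centered_log2fc", "gene_id", "log2fc", "decile", "dev", "e", "condition",
  "replicate", "n_inframe"
))
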