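#' @importFrom data.table as.data.table setorder setnames copy .N .SD
#' @importFrom stats quantile
#' @importFrom methods as
NULL

.datatable.aware <- TRUE
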