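# Hand-buildable fixtures shared across tests.

# 30 nt toy reference with CpG sites at 0-based 5 and 20 and three extra
# non-CpG cytosines (0-based 10, 14, 25); no CCWGG.
#            0123456789012345678901234567890
TOY30 <- "AATTACGTTACATTCAGTTACGATTCATTA"

toy_region <- function() reference_region("toy30", TOY30)

# region carrying three CCAGG/CCTGG occurrences for dcm tests
dcm_region <- function() {
  reference_region("dcmtoy",
    paste0("AATTAACCAGGTTATAACCTGGTTATAACCAGGTTATTACGTTATTAAGG"))
}

# site table with chosen counts
site_table <- function(m, n, positions = seq_along(m) * 10L, n_min = 1L) {
  data.frame(site = positions, m = m, n = n, efficiency = m / n,
             low_n = n < n_min)
}

site_columns_t <- function(calls) grep("^s[0-9]+$", names(calls))

nw_t <- function(counts, w) counts$counts[[nchar(w)]][w]
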