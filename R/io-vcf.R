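# Minimal single-sample, sites-only VCF 4.2 writer/reader.
#
# The INFO keys record both the raw caller evidence (DP/AO/AF) and the values
# re-evaluated after read-end removal (AO_CORE/AF_CORE), so every filter
# decision is auditable from the emitted file.

VCF_FILTER_LABELS <- c(
  in_normal    = "Variant also called in the matched normal sample",
  end_read     = "No supporting read remains after removing reads where the variant lies within the terminal 15% of aligned bases",
  multiallelic = "More than 2 distinct variant alleles observed at the site",
  min_depth    = "Site covered by fewer than the minimum number of reads",
  low_af       = "Re-evaluated allele frequency below the 2% reporting floor",
  tier_support = "Insufficient supporting reads for the allele-frequency tier (10 reads at AF 2-5%, 25 reads above 5%)"
)

# full double precision so write -> read round-trips bit-exactly
fmt_num <- function(x) sprintf("%.17g", x)

#' Write variant records to a VCF 4.2 file
#'
#' @param records A tibble of variant records or filter verdicts with columns
#'   `ref_name`, `pos0` (0-based; written 1-based), `ref_allele`, `alt_allele`,
#'   `depth`, `alt_reads`, `af`, and optionally `ao_core`, `af_core` and
#'   `trail` (list of failed-filter labels; empty means PASS). Must be sorted
#'   by (`ref_name`, `pos0`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  req <- c("ref_name", "pos0", "ref_allele", "alt_allele", "depth", "alt_reads", "af")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop_format("records lack column(s): %s", paste(miss, collapse = ", "))
  if (nrow(records) > 1L) {
    o <- order(records$ref_name, records$pos0)
    if (!identical(o, seq_len(nrow(records)))) {
      abort("records must be sorted by (ref_name, pos0) before writing VCF",
            class = "somaticsieve_order_error")
    }
  }
  pick <- function(col, fallback) {
    if (col %in% names(records)) records[[col]] else fallback
  }
  ao_core <- pick("ao_core", records$alt_reads)
  af_core <- pick("af_core", records$af)
  trail <- pick("trail", rep(list(character()), nrow(records)))
  filt <- map_chr(trail, ~ if (length(.x) == 0L) "PASS" else paste(.x, collapse = ";"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticsieve",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth at the site\">",
    "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Reads supporting the alternate allele\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency AO/DP\">",
    "##INFO=<ID=AO_CORE,Number=1,Type=Integer,Description=\"Alternate reads after removing reads with the variant in the terminal 15% of aligned bases\">",
    "##INFO=<ID=AF_CORE,Number=1,Type=Float,Description=\"Allele frequency re-evaluated after read-end removal\">",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">", names(VCF_FILTER_LABELS), VCF_FILTER_LABELS),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf("DP=%d;AO=%d;AF=%s;AO_CORE=%d;AF_CORE=%s",
                  as.integer(records$depth), as.integer(records$alt_reads),
                  fmt_num(records$af), as.integer(ao_core), fmt_num(af_core))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  records$ref_name, records$pos0 + 1L,
                  records$ref_allele, records$alt_allele, filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file written by [write_vcf()]
#'
#' @param path Path to a VCF file.
#' @return A tibble with columns `ref_name`, `pos0`, `ref_allele`,
#'   `alt_allele`, `depth`, `alt_reads`, `af`, `ao_core`, `af_core` and
#'   `trail` (list-column; empty character vector for PASS records).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_format("VCF file '%s' does not exist", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop_format("'%s' is not a VCF file", path)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- tibble(ref_name = character(), pos0 = integer(),
                  ref_allele = character(), alt_allele = character(),
                  depth = integer(), alt_reads = integer(), af = double(),
                  ao_core = integer(), af_core = double(), trail = list())
  if (!length(body)) return(empty)
  f <- str_split(body, "\t")
  if (any(lengths(f) < 8L)) stop_format("VCF '%s': line with fewer than 8 fields", path)
  info_get <- function(info, key) {
    m <- str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  info <- map_chr(f, 8L)
  tibble(
    ref_name = map_chr(f, 1L),
    pos0 = as.integer(map_chr(f, 2L)) - 1L,
    ref_allele = map_chr(f, 4L),
    alt_allele = map_chr(f, 5L),
    depth = as.integer(info_get(info, "DP")),
    alt_reads = as.integer(info_get(info, "AO")),
    af = as.double(info_get(info, "AF")),
    ao_core = as.integer(info_get(info, "AO_CORE")),
    af_core = as.double(info_get(info, "AF_CORE")),
    trail = map(map_chr(f, 7L),
                ~ if (.x == "PASS" || .x == ".") character() else strsplit(.x, ";")[[1]])
  )
}
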