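#' Read an EIGENSTRAT genotype trio
#'
#' Reads the plain-text EIGENSTRAT dialect: a `.geno` file with one row per
#' SNP and one digit per individual (0/1/2 copies of allele1, 9 = missing), a
#' whitespace-separated `.snp` file (id, chromosome, genetic position,
#' physical position, allele1, allele2) and a `.ind` file (id, sex,
#' population). Dimensions are cross-validated across the three files.
#'
#' @param prefix Path prefix; `<prefix>.geno`, `<prefix>.snp` and
#'   `<prefix>.ind` are read. Individual paths can be given instead via
#'   `geno`, `snp`, `ind`.
#' @param geno,snp,ind Explicit file paths (override `prefix`).
#' @param pseudo_haploid Logical vector or scalar flagging pseudo-haploid
#'   individuals; `NULL` (default) infers the flag per individual as "carries
#'   no heterozygous call".
#' @return A [geno_matrix()].
#' @export
read_eigenstrat <- function(prefix = NULL, geno = NULL, snp = NULL, ind = NULL,
                            pseudo_haploid = NULL) {
  geno <- geno %||% paste0(prefix, ".geno")
  snp <- snp %||% paste0(prefix, ".snp")
  ind <- ind %||% paste0(prefix, ".ind")
  for (f in c(geno, snp, ind)) if (!file.exists(f)) stop_pk("file not found: ", f)

  ind_tbl <- read_ws_table(ind, c("id", "sex", "population"))
  snp_tbl <- read_ws_table(snp, c("snp_id", "chrom", "genetic_pos",
                                  "physical_pos", "allele1", "allele2"))
  snp_tbl$genetic_pos <- as.numeric(snp_tbl$genetic_pos)
  snp_tbl$physical_pos <- as.integer(snp_tbl$physical_pos)

  lines <- readLines(geno)
  if (length(lines) != nrow(snp_tbl)) {
    stop_pk(".geno has ", length(lines), " rows but .snp has ", nrow(snp_tbl),
            " (first mismatch at .geno line ", min(length(lines), nrow(snp_tbl)) + 1, ")")
  }
  widths <- nchar(lines)
  bad_w <- which(widths != nrow(ind_tbl))
  if (length(bad_w) > 0) {
    stop_pk(".geno line ", bad_w[1], " has width ", widths[bad_w[1]],
            " but .ind has ", nrow(ind_tbl), " rows")
  }
  chars <- unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE)
  ok <- chars %in% c("0", "1", "2", "9")
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop_pk("non-genotype character '", chars[i], "' in .geno at line ",
            (i - 1) %/% nrow(ind_tbl) + 1, ", column ", (i - 1) %% nrow(ind_tbl) + 1)
  }
  calls <- matrix(as.integer(chars), nrow = length(lines), ncol = nrow(ind_tbl),
                  byrow = TRUE)
  calls[calls == 9L] <- NA_integer_

  if (is.null(pseudo_haploid)) {
    pseudo_haploid <- colSums(calls == 1L, na.rm = TRUE) == 0
  }
  ind_tbl$pseudo_haploid <- rep_len(pseudo_haploid, nrow(ind_tbl))
  geno_matrix(calls, snp_tbl, ind_tbl)
}

read_ws_table <- function(path, cols) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(as_tibble(setNames(rep(list(character()), length(cols)), cols)))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != length(cols))) {
    stop_pk(path, " line ", which(nf != length(cols))[1], " has ",
            nf[nf != length(cols)][1], " fields, expected ", length(cols))
  }
  m <- do.call(rbind, parts)
  colnames(m) <- cols
  as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
}

#' Write an EIGENSTRAT genotype trio
#'
#' Output is byte-deterministic (LF line endings, fixed field formatting) and
#' round-trips through [read_eigenstrat()].
#'
#' @param g A [geno_matrix()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_eigenstrat <- function(g, prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  calls <- g$calls
  ph <- g$ind$pseudo_haploid
  if (any(ph)) {
    if (any(calls[, ph, drop = FALSE] == 1L, na.rm = TRUE)) {
      stop_pk("pseudo-haploid individual carries call 1; refusing to write")
    }
  }
  calls[is.na(calls)] <- 9L
  geno_lines <- apply(calls, 1, paste, collapse = "")
  if (nrow(calls) == 0) geno_lines <- character()
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  writeLines(geno_lines, paste0(prefix, ".geno"))
  snp_lines <- sprintf("%s\t%s\t%s\t%d\t%s\t%s",
                       g$snp$snp_id, g$snp$chrom,
                       format_num(g$snp$genetic_pos), g$snp$physical_pos,
                       g$snp$allele1, g$snp$allele2)
  writeLines(snp_lines, paste0(prefix, ".snp"))
  ind_lines <- sprintf("%s\t%s\t%s", g$ind$id, g$ind$sex, g$ind$population)
  writeLines(ind_lines, paste0(prefix, ".ind"))
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  trimws(out)
}
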