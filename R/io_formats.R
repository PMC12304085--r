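#' Write and read genotypes in genepop format
#'
#' Standard genepop dialect: a title line, one locus name per line, then one
#' `POP` block per deme with lines `id ,  0101 0102 ...`. Genotypes are
#' written as two-digit (default) or three-digit allele codes; allele 1 is
#' the ancestral/reference allele and allele 2 the derived/alternate one,
#' so a 0/1/2 dosage becomes `0101`/`0102`/`0202`. Missing genotypes are
#' `0000` (or `000000`).
#'
#' @param x A [genotype_matrix()].
#' @param path Output file.
#' @param digits 2 or 3 digit allele codes.
#' @param title Title line content.
#' @return `write_genepop()` returns `path` invisibly; `read_genepop()` a
#'   [genotype_matrix()] (dosage of allele 2, demes from POP blocks).
#' @export
write_genepop <- function(x, path, digits = 2, title = "nesim export") {
  stopifnot(inherits(x, "genotype_matrix"), digits %in% c(2, 3))
  a1 <- formatC(1, width = digits, flag = "0")
  a2 <- formatC(2, width = digits, flag = "0")
  a0 <- strrep("0", digits)
  codes <- c(paste0(a1, a1), paste0(a1, a2), paste0(a2, a2))
  gm <- matrix(codes[x$g + 1L], nrow(x$g))
  gm[is.na(x$g)] <- strrep("0", 2 * digits)
  loc_names <- locus_ids(x)
  deme <- if ("deme" %in% names(x$samples)) x$samples$deme else
    rep(1L, nrow(x$g))
  lines <- c(title, loc_names)
  for (d in sort(unique(deme))) {
    lines <- c(lines, "POP")
    rows <- which(deme == d)
    lines <- c(lines, paste0(x$samples$id[rows], " ,  ",
                             apply(gm[rows, , drop = FALSE], 1, paste,
                                   collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

locus_ids <- function(x) {
  if ("id" %in% names(x$loci)) as.character(x$loci$id) else
    paste0("chr", x$loci$chrom, "_", x$loci$pos)
}

#' @rdname write_genepop
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("genepop: file too short", call. = FALSE)
  body <- lines[-1]
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("genepop: no POP line found", call. = FALSE)
  loc_names <- trimws(unlist(strsplit(body[seq_len(first_pop - 1)], ",")))
  n_loci <- length(loc_names)
  ids <- character(0); demes <- integer(0); rows <- list()
  deme <- 0L
  for (i in seq(first_pop, length(body))) {
    if (is_pop[i]) { deme <- deme + 1L; next }
    parts <- strsplit(body[i], ",")[[1]]
    if (length(parts) < 2) {
      stop("genepop: malformed record at line ", i + 1L, call. = FALSE)
    }
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gts) != n_loci) {
      stop("genepop: line ", i + 1L, " has ", length(gts), " genotypes, ",
           "expected ", n_loci, call. = FALSE)
    }
    w <- nchar(gts[1])
    if (!w %in% c(4, 6) || any(nchar(gts) != w)) {
      stop("genepop: line ", i + 1L, ": allele codes must be uniformly 2- ",
           "or 3-digit", call. = FALSE)
    }
    half <- w / 2
    al1 <- as.integer(substr(gts, 1, half))
    al2 <- as.integer(substr(gts, half + 1, w))
    dose <- (al1 == 2L) + (al2 == 2L)
    dose[al1 == 0L | al2 == 0L] <- NA_integer_
    ids <- c(ids, id); demes <- c(demes, deme)
    rows[[length(rows) + 1L]] <- dose
  }
  g <- do.call(rbind, rows)
  loci <- parse_locus_ids(loc_names)
  genotype_matrix(g, loci, tibble::tibble(id = ids, deme = demes))
}

parse_locus_ids <- function(loc_names) {
  m <- regmatches(loc_names, regexec("^chr(.+)_([0-9]+)$", loc_names))
  ok <- lengths(m) == 3
  chrom <- ifelse(ok, vapply(m, function(v) if (length(v) == 3) v[2] else NA,
                             ""), NA)
  pos <- ifelse(ok, vapply(m, function(v) if (length(v) == 3) v[3] else NA,
                           ""), NA)
  if (all(ok)) {
    chrom_num <- suppressWarnings(as.integer(chrom))
    tibble::tibble(
      chrom = if (!anyNA(chrom_num)) chrom_num else chrom,
      pos = as.integer(pos), id = loc_names
    )
  } else {
    tibble::tibble(chrom = 1L, pos = seq_along(loc_names), id = loc_names)
  }
}

#' Write and read genotypes as PLINK PED/MAP
#'
#' `<prefix>.map` has columns chromosome, locus id, genetic position (0) and
#' bp position, sorted by (chromosome, position); `<prefix>.ped` has family
#' (deme), individual id, father, mother, sex, phenotype and two allele
#' columns per locus (`A` = ancestral, `T` = derived, `0` = missing).
#'
#' @param x A [genotype_matrix()].
#' @param prefix Output path prefix (without extension).
#' @return `write_ped_map()` returns the prefix invisibly; `read_ped_map()`
#'   a [genotype_matrix()].
#' @export
write_ped_map <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (anyNA(x$loci$chrom) || anyNA(x$loci$pos)) {
    stop("PED/MAP export needs chromosome and position for every locus; ",
         "missing for loci ",
         paste(utils::head(which(is.na(x$loci$chrom) | is.na(x$loci$pos)), 5),
               collapse = ", "), call. = FALSE)
  }
  ord <- order(x$loci$chrom, x$loci$pos)
  loci <- x$loci[ord, ]
  g <- x$g[, ord, drop = FALSE]
  map <- paste(loci$chrom, locus_ids(list(loci = loci)), 0, loci$pos,
               sep = "\t")
  writeLines(map, paste0(prefix, ".map"))
  anc <- if ("ancestral" %in% names(loci)) loci$ancestral else "A"
  der <- if ("derived" %in% names(loci)) loci$derived else "T"
  n <- nrow(g); L <- ncol(g)
  a1 <- matrix(rep(anc, each = n), n, L)
  a2 <- matrix(rep(der, each = n), n, L)
  first <- ifelse(g >= 1L, a2, a1)
  second <- ifelse(g == 2L, a2, a1)
  first[is.na(g)] <- "0"; second[is.na(g)] <- "0"
  geno <- matrix(paste(first, second), n, L)
  deme <- if ("deme" %in% names(x$samples)) x$samples$deme else 1L
  sex <- if ("sex" %in% names(x$samples))
    ifelse(x$samples$sex %in% c("M", 1), 1L, 2L) else 0L
  lead <- paste(deme, x$samples$id, 0, 0, sex, -9, sep = "\t")
  writeLines(paste(lead, apply(geno, 1, paste, collapse = "\t"), sep = "\t"),
             paste0(prefix, ".ped"))
  invisible(prefix)
}

#' @rdname write_ped_map
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "\t",
                           colClasses = "character")
  L <- nrow(map)
  if (ncol(ped) != 6 + L) stop("PED/MAP: column count mismatch", call. = FALSE)
  n <- nrow(ped)
  al <- as.vector(as.matrix(ped[, -(1:6), drop = FALSE]))  # column-major
  sp <- regexpr(" ", al, fixed = TRUE)
  p1 <- substr(al, 1, sp - 1)
  p2 <- substr(al, sp + 1, nchar(al))
  der <- rep("T", n * L)
  g <- matrix((p1 == der) + (p2 == der), n, L)
  g[matrix(p1 == "0" | p2 == "0", n, L)] <- NA
  genotype_matrix(g, tibble::tibble(chrom = map$chrom, pos = map$pos,
                                    id = map$id),
                  tibble::tibble(id = ped[, 2], deme = ped[, 1]))
}

#' Write and read genotypes as VCF
#'
#' Minimal VCF 4.2 with unphased diploid `GT` fields, 1-based positions,
#' the ancestral allele as `REF` and the derived allele as `ALT`. The
#' bundled reader handles this dialect (biallelic sites, `GT` first).
#'
#' @param x A [genotype_matrix()].
#' @param path Output file.
#' @return `write_vcf()` returns `path` invisibly; `read_vcf()` a
#'   [genotype_matrix()].
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (anyNA(x$loci$chrom) || anyNA(x$loci$pos)) {
    stop("VCF export needs chromosome and position for every locus",
         call. = FALSE)
  }
  ord <- order(x$loci$chrom, x$loci$pos)
  loci <- x$loci[ord, ]
  g <- t(x$g[, ord, drop = FALSE])  # loci x individuals
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g))
  gt[is.na(g)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nesim",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", as.character(x$samples$id)), collapse = "\t")
  )
  anc <- if ("ancestral" %in% names(loci)) loci$ancestral else "A"
  der <- if ("derived" %in% names(loci)) loci$derived else "T"
  body <- paste(loci$chrom, loci$pos, locus_ids(list(loci = loci)), anc, der,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1) stop("VCF: missing #CHROM header line", call. = FALSE)
  cols <- strsplit(hdr, "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  f <- strsplit(body, "\t")
  L <- length(f)
  chrom <- vapply(f, `[`, "", 1)
  pos <- as.integer(vapply(f, `[`, "", 2))
  ref <- vapply(f, `[`, "", 4)
  alt <- vapply(f, `[`, "", 5)
  g <- matrix(NA_integer_, length(ids), L)
  for (j in seq_len(L)) {
    gt <- sub(":.*$", "", f[[j]][-(1:9)])
    gt <- gsub("|", "/", gt, fixed = TRUE)
    dose <- ifelse(gt == "0/0", 0L,
                   ifelse(gt %in% c("0/1", "1/0"), 1L,
                          ifelse(gt == "1/1", 2L, NA_integer_)))
    g[, j] <- dose
  }
  chrom_num <- suppressWarnings(as.integer(chrom))
  genotype_matrix(
    g,
    tibble::tibble(chrom = if (!anyNA(chrom_num)) chrom_num else chrom,
                   pos = pos, ancestral = ref, derived = alt),
    tibble::tibble(id = ids)
  )
}
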