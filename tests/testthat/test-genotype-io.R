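test_that("PLINK bed/bim/fam round trip is lossless, including missing", {
  X <- matrix(c(0, 1, 2, NA, 2, 0,
                1, 1, 0, 2, NA, 2,
                2, 0, 1, 1, 0, 0), nrow = 3, byrow = TRUE)
  G <- toy_G(X)
  pre <- file.path(withr::local_tempdir(), "panel")
  write_plink(G, pre)
  G2 <- read_plink(pre)
  expect_identical(unname(G2$dosages), unname(G$dosages))
  expect_equal(G2$markers$id, G$markers$id)
  expect_equal(G2$markers$pos, G$markers$pos)
  expect_equal(G2$accession_ids, G$accession_ids)
})

test_that("PLINK writer rejects fractional dosages and non-bed payloads error", {
  G <- toy_G(matrix(c(0.5, 1, 1, 2), 2, 2))
  expect_error(write_plink(G, tempfile()), "fractional")
  bad <- tempfile(fileext = "")
  writeBin(as.raw(c(1, 2, 3)), paste0(bad, ".bed"))
  writeLines("1\tm1\t0\t100\tA\tG", paste0(bad, ".bim"))
  writeLines("s1\ts1\t0\t0\t0\t-9", paste0(bad, ".fam"))
  expect_error(read_plink(bad), "SNP-major")
})

test_that("VCF genotypes convert to alternate-allele dosages", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t1|0\t0/0"
  ), vcf)
  G <- read_vcf_genotypes(vcf)
  expect_equal(unname(G$dosages["S1", ]), c(0, NA))
  expect_equal(unname(G$dosages["S2", ]), c(1, 1))
  expect_equal(unname(G$dosages["S3", ]), c(2, 0))
  expect_equal(G$markers$class, c("SNP", "SNP"))
  expect_equal(G$markers$pos, c(100L, 200L))
})

test_that("combined SNP + SV reading concatenates with class metadata", {
  dir <- withr::local_tempdir()
  snpX <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3)
  Gsnp <- toy_G(snpX)
  write_plink(Gsnp, file.path(dir, "snp"))
  svX <- matrix(c(0, 1, 1), ncol = 1)
  Gsv <- genotype_matrix(svX, data.frame(id = "sv1", chrom = "2", pos = 500,
                                         class = "DEL"),
                         Gsnp$accession_ids)
  write_sv_tsv(Gsv, file.path(dir, "sv.tsv"))
  G <- read_genotypes(file.path(dir, "snp"), file.path(dir, "sv.tsv"))
  expect_equal(dim(G$dosages), c(3L, 3L))
  expect_equal(G$markers$class, c("SNP", "SNP", "DEL"))

  # accession mismatch errors and names the offenders
  Gsv_bad <- genotype_matrix(svX, data.frame(id = "sv1", chrom = "2", pos = 500,
                                             class = "DEL"),
                             c("acc1", "acc2", "OTHER"))
  write_sv_tsv(Gsv_bad, file.path(dir, "svbad.tsv"))
  expect_error(read_genotypes(file.path(dir, "snp"), file.path(dir, "svbad.tsv")),
               "OTHER")
})

test_that("simulated panel round-trips through the writers bit-identically", {
  sim <- small_panel(seed = 20, markers = c(SNP = 40, DEL = 10, DUP = 5))
  dir <- withr::local_tempdir()
  write_plink(sim$genotypes, file.path(dir, "p"))
  write_sv_tsv(sim$genotypes, file.path(dir, "sv.tsv"))
  G2 <- read_genotypes(file.path(dir, "p"), file.path(dir, "sv.tsv"))
  snp_cols <- sim$genotypes$markers$class == "SNP"
  reord <- c(which(snp_cols), which(!snp_cols))
  expect_identical(unname(G2$dosages),
                   unname(sim$genotypes$dosages[, reord]))
  expect_equal(G2$markers$id, sim$genotypes$markers$id[reord])
})

test_that("malformed SV class labels are rejected", {
  expect_error(genotype_matrix(matrix(0, 2, 1),
                               data.frame(id = "x", chrom = "1", pos = 1,
                                          class = "WEIRD")),
               "malformed")
})

test_that("phenotype tables round-trip with trait kinds", {
  P <- phenotype_table(c("a", "b", "c"), c("IND", "IND", "ARO"),
                       data.frame(gw = c(1.2, NA, 3.1), cd = c(1, 2, 2)),
                       c(gw = "quantitative", cd = "binary"))
  path <- tempfile(fileext = ".tsv")
  write_phenotypes(P, path)
  P2 <- read_phenotypes(path)
  expect_equal(P2$traits$gw, P$traits$gw)
  expect_equal(P2$traits$cd, P$traits$cd)
  expect_equal(P2$kinds, P$kinds)
  expect_equal(P2$group, P$group)
})

test_that("marker filtering removes low-MAF and high-missingness markers", {
  X <- rbind(c(0, 0, 2, 1, 0),
             c(0, 1, 2, NA, 0),
             c(0, 2, 2, 1, 1),
             c(0, 1, 2, 0, 0))
  G <- toy_G(X)
  res <- filter_markers(G, maf_min = 0.01, max_missing = 0.01)
  lg <- res$log
  # monomorphic columns 1 and 3 removed for MAF, column 4 for missingness
  expect_setequal(lg$id, c("m001", "m003", "m004"))
  expect_equal(lg$reason[lg$id == "m001"], "MAF")
  expect_equal(lg$reason[lg$id == "m004"], "missing_rate")
  expect_equal(ncol(res$genotypes$dosages), 2L)
})

test_that("the MAF rule is strict at the threshold and folded for SVs", {
  # SNP at exactly MAF 0.01 is removed (rule: MAF <= 0.01 filtered out)
  X <- cbind(c(rep(0, 99), 2), c(rep(0, 50), rep(2, 50)))
  G <- toy_G(X)
  res <- filter_markers(G, maf_min = 0.01)
  expect_equal(res$log$id, "m001")
  # SV presence frequency folds: f = 0.8 -> folded 0.2, kept
  sv <- genotype_matrix(cbind(rep(c(1, 1, 1, 1, 0), 4)),
                        data.frame(id = "sv", chrom = "1", pos = 1, class = "DEL"))
  expect_equal(nrow(filter_markers(sv)$log), 0L)
})

test_that("a simulated panel with planted violations loses exactly those markers", {
  sim <- small_panel(seed = 21, n = c(A = 100),
                     markers = c(SNP = 800, DEL = 200), fst = 0.05)
  G <- sim$genotypes
  res0 <- filter_markers(G)
  G <- res0$genotypes  # start from a clean panel
  m <- ncol(G$dosages)
  set.seed(99)
  viol <- sort(sample(m, 37))
  X <- G$dosages
  half <- viol[1:18]; rest <- viol[19:37]
  X[, half] <- 0                      # monomorphic -> MAF violation
  X[1:3, rest] <- NA                  # 3% missing  -> missingness violation
  G2 <- genotype_matrix(X, G$markers, G$accession_ids)
  res <- filter_markers(G2)
  expect_equal(nrow(res$log), 37L)
  expect_setequal(res$log$id, G$markers$id[viol])
})

test_that("filtering is idempotent", {
  sim <- small_panel(seed = 22)
  once <- filter_markers(sim$genotypes)
  twice <- filter_markers(once$genotypes)
  expect_equal(nrow(twice$log), 0L)
  expect_identical(twice$genotypes$dosages, once$genotypes$dosages)
})

test_that("filtering everything raises an empty-panel error", {
  G <- toy_G(matrix(0, 4, 3))
  expect_error(filter_markers(G), "empty panel")
})

test_that("mean imputation fills SNPs with means and SVs with rounded means", {
  X <- cbind(c(0, 2, NA), c(1, 1, 1))
  G <- toy_G(X)
  Gi <- impute_missing(G)
  expect_equal(Gi$dosages[3, 1], 1.0)
  sv <- genotype_matrix(cbind(c(0, 1, 1, NA)),
                        data.frame(id = "s", chrom = "1", pos = 1, class = "DEL"))
  expect_equal(impute_missing(sv)$dosages[4, 1], 1)   # mean 2/3 rounds to 1
  # no missing -> identity
  G0 <- toy_G(matrix(c(0, 1, 2, 0), 2, 2))
  expect_identical(impute_missing(G0)$dosages, G0$dosages)
  # imputation preserves SNP column means
  expect_equal(mean(Gi$dosages[, 1]), mean(X[, 1], na.rm = TRUE))
})

test_that("imputation respects training-row statistics", {
  X <- cbind(c(0, 0, 2, 2, NA))
  G <- toy_G(X)
  Gi <- impute_missing(G, train_rows = 1:2)
  expect_equal(Gi$dosages[5, 1], 0)  # train mean is 0
})

test_that("phenotype transforms bin ordinals and log-transform traits", {
  P <- phenotype_table(paste0("a", 1:5), rep("IND", 5),
                       data.frame(ls = c(1, 3, 5, 7, 9),
                                  ttf = c(100, 80, 120, 90, 110)),
                       c(ls = "quantitative", ttf = "quantitative"))
  P2 <- transform_phenotypes(P, list(bin_ordinal = "ls", log = "ttf"))
  expect_equal(P2$traits$ls_class, c(1, 2, 2, 2, 2))
  expect_equal(P2$kinds[["ls_class"]], "binary")
  expect_equal(P2$traits$ttf_log[1], log(100))
  expect_equal(P2$traits$ttf_log[1], 4.60517, tolerance = 1e-5)
  # originals preserved
  expect_equal(P2$traits$ls, P$traits$ls)
  # empty rules -> unchanged
  P3 <- transform_phenotypes(P, list())
  expect_identical(P3$traits, P$traits)
})

test_that("log transform rejects nonpositive values naming the accession", {
  P <- phenotype_table(c("accA", "accB"), c("IND", "IND"),
                       data.frame(ttf = c(10, 0)), c(ttf = "quantitative"))
  expect_error(transform_phenotypes(P, list(log = "ttf")), "accB")
})
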