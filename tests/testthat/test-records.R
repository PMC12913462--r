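# Reading, curation and HLA normalization.

test_that("peptide tables round-trip through TSV and CSV", {
  tab <- toy_peptide_table()
  for (dialect in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_peptide_table(tab, path, dialect = dialect)
    back <- read_peptide_table(path, dialect = dialect)
    expect_equal(as.data.frame(back), as.data.frame(tab))
  }
})

test_that("a header-only file yields zero records and missing columns error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("record_id\tmutant_peptide\thla_allele\tlabel", path)
  expect_equal(nrow(read_peptide_table(path)), 0)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutant_peptide\thla_allele", "SIINFEKL\tHLA-A*02:01"), path2)
  expect_error(read_peptide_table(path2), class = "neorank_schema_error",
               regexp = "label")
})

test_that("unparseable feature cells report the row index", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutant_peptide\thla_allele\tlabel\tF1",
               "SIINFEKL\tHLA-A*02:01\timmunogenic\t1.5",
               "KEDEALYFV\tHLA-A*01:01\timmunogenic\toops"), path)
  expect_error(read_peptide_table(path), class = "neorank_value_error",
               regexp = "row 2")
})

test_that("curation keeps 8-11-mers over the amino-acid alphabet", {
  tab <- tibble::tibble(
    mutant_peptide = c(strrep("A", 7), strrep("A", 8), random_peptide(9),
                       strrep("C", 11), strrep("A", 12)),
    hla_allele = "HLA-A*02:01",
    label = "immunogenic"
  )
  # distinct peptides so deduplication does not interfere
  cur <- curate(tab)
  expect_equal(nrow(cur), 3)
  expect_setequal(nchar(cur$mutant_peptide), c(8, 9, 11))
  rep <- curation_report(cur)
  expect_equal(rep$count[rep$rule == "length_out_of_bounds"], 2)
})

test_that("alphabet violations and incomplete records are counted per rule", {
  tab <- tibble::tibble(
    mutant_peptide = c("SIINFEKL", "SIINFEKB", NA),
    hla_allele = c("HLA-A*02:01", "HLA-A*02:01", "HLA-A*02:01"),
    label = c("immunogenic", "immunogenic", "immunogenic")
  )
  cur <- curate(tab)
  rep <- curation_report(cur)
  expect_equal(nrow(cur), 1)
  expect_equal(rep$count[rep$rule == "invalid_alphabet"], 1)
  expect_equal(rep$count[rep$rule == "incomplete"], 1)
})

test_that("duplicate pairs keep the first occurrence and report label conflicts", {
  tab <- tibble::tibble(
    mutant_peptide = c("SIINFEKL", "SIINFEKL", "SIINFEKL"),
    hla_allele = c("HLA-A*02:01", "A0201", "HLA-A*02:01"),
    label = c("immunogenic", "non_immunogenic", "immunogenic")
  )
  cur <- curate(tab)
  expect_equal(nrow(cur), 1)
  expect_equal(cur$label, "immunogenic")
  rep <- curation_report(cur)
  expect_equal(rep$count[rep$rule == "duplicate_pair"], 2)
  expect_equal(rep$count[rep$rule == "label_conflict_among_duplicates"], 1)
})

test_that("curation is idempotent and removal counts partition the input", {
  set.seed(7)
  tab <- tibble::tibble(
    mutant_peptide = c(vapply(sample(6:13, 30, replace = TRUE), random_peptide,
                              character(1))),
    hla_allele = sample(c("HLA-A*02:01", "B0702"), 30, replace = TRUE),
    label = sample(c("immunogenic", "non_immunogenic"), 30, replace = TRUE)
  )
  cur1 <- curate(tab)
  cur2 <- curate(cur1)
  expect_equal(cur1$mutant_peptide, cur2$mutant_peptide)
  expect_equal(cur1$hla_allele, cur2$hla_allele)
  rep <- curation_report(cur1)
  removable <- rep$count[rep$rule %in% c("incomplete", "invalid_alphabet",
                                         "length_out_of_bounds", "duplicate_pair")]
  expect_equal(nrow(cur1) + sum(removable), nrow(tab))
})

test_that("HLA normalization canonicalizes common alias spellings", {
  aliases <- c(
    "HLA-A*01:01" = "HLA-A*01:01",
    "A0101"       = "HLA-A*01:01",
    "a*1:1"       = "HLA-A*01:01",
    "HLA-A01:01"  = "HLA-A*01:01",
    "A*01:01"     = "HLA-A*01:01",
    "b4402"       = "HLA-B*44:02",
    "HLA-B44:02"  = "HLA-B*44:02",
    "C0702"       = "HLA-C*07:02",
    "hla-a*02:01" = "HLA-A*02:01",
    "DRB10401"    = "HLA-DRB1*04:01"
  )
  expect_equal(normalize_hla(names(aliases)), unname(aliases))
  # idempotence
  expect_equal(normalize_hla(unname(aliases)), unname(aliases))
  expect_error(normalize_hla(""), class = "neorank_normalization_error")
  expect_error(normalize_hla("notanallele!"), class = "neorank_normalization_error")
})

test_that("FASTA reading uppercases, takes first header token, rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "mkvl", "AERT",
               ">prot2", "GGGG"), path)
  seqs <- read_fasta(path)
  expect_equal(names(seqs), c("prot1", "prot2"))
  expect_equal(unname(seqs["prot1"]), "MKVLAERT")

  # byte-level reference parse of a wrapped record
  lines <- readLines(path)
  manual <- toupper(paste(lines[2:3], collapse = ""))
  expect_equal(unname(seqs["prot1"]), manual)

  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">dup", "AAAA", ">dup", "CCCC"), path2)
  expect_error(read_fasta(path2), class = "neorank_io_error", regexp = "dup")
})

test_that("variant tables validate coordinates and substitutions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tref_aa\talt_aa\tgene",
               "P1\t25\tA\tV\tTP53"), path)
  v <- read_variant_table(path)
  expect_equal(v$position, 25L)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tref_aa\talt_aa",
               "P1\t25\tA\tA"), path2)
  expect_error(read_variant_table(path2), class = "neorank_value_error")
})

test_that("missense variants parse from a VCF protein-consequence tag", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=PCSQ,Number=1,Type=String,Description="Protein consequence">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1000\t.\tG\tT\t50\tPASS\tPCSQ=P1:p.A25V",
    "chr1\t2000\t.\tC\tA\t50\tPASS\tPCSQ=P2:p.R10Q",
    "chr1\t3000\t.\tC\tA\t50\tPASS\tOTHER=1"
  ), path)
  v <- read_variants_vcf(path)
  expect_equal(nrow(v), 2)
  expect_equal(v$protein_id, c("P1", "P2"))
  expect_equal(v$position, c(25L, 10L))
  expect_equal(v$alt_aa, c("V", "Q"))
})
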