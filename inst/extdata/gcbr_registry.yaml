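# Global Core Biodata Resource registry (2024 roster, 52 resources).
#
# Accession patterns are identifiers.org-style Local Unique Identifier (LUI)
# regular expressions. Where the public LUI pattern is too general to be used
# bare in free text (bare digit runs, arbitrary short tokens), a conservative
# equivalent is recorded here instead; each such choice is annotated on the
# entry. Patterns are stored as SOURCE strings; compilation (case folding,
# word-boundary anchoring, tolerance for one space after a namespace colon)
# happens in the matcher.
#
# prefix_required entries match only when the accession is immediately
# preceded by one of prefix_tokens plus ":" (optionally followed by a single
# space), e.g. "col:4QHKG", "UniProt:Q8VRN4".
version_label: gcbr-2024
resources:
- resource_id: alliance_genome
  display_name: Alliance of genome resources
- resource_id: bacdive
  display_name: BacDive
  # public LUI is a bare digit run; conservative equivalent embeds the
  # namespace prefix so that arbitrary integers do not match.
  accession_pattern: 'BACDIVE:\d+'
  example_accession: 'BACDIVE:131392'
- resource_id: bar
  display_name: Bio-analytic resource for plant biology
- resource_id: bgee
  display_name: Bgee
  # Bgee reuses Ensembl and FlyBase gene identifiers; digit-count left open
  # so that truncated FlyBase-style identifiers still match Bgee only.
  accession_pattern: '(ENS[A-Z]{0,4}[FPTG]|FB[a-z]{2})\d+(\.\d+)?'
  example_accession: FBgn0036915
- resource_id: brenda
  display_name: BRENDA
  accession_pattern: '[1-7]\.\d+\.\d+\.\d+'
  example_accession: 7.2.1.1
  name_excluded: yes
  name_exclusion_reason: confused with first names or surnames
- resource_id: col
  display_name: Catalogue of life
  name_variants:
  - Catalog of life
  accession_pattern: '[23456789BCDFGHJKLMNPQRSTVWXYZ]{1,6}'
  example_accession: 4QHKG
  prefix_required: yes
  prefix_tokens:
  - col
- resource_id: cath
  display_name: CATH
  accession_pattern: '[1-6]\.\d+\.\d+\.\d+'
  example_accession: 1.10.8.10
  name_excluded: yes
  name_exclusion_reason: confused with the abbreviation of catheter, e.g. "cath lab"
- resource_id: cellosaurus
  display_name: Cellosaurus
  accession_pattern: 'CVCL_[A-Z0-9]{4}'
  example_accession: CVCL_0030
- resource_id: chebi
  display_name: ChEBI
  accession_pattern: 'CHEBI:\d+'
  example_accession: 'CHEBI:18034'
- resource_id: chembl
  display_name: ChEMBL
  accession_pattern: 'CHEMBL\d+'
  example_accession: CHEMBL1148970
- resource_id: civic
  display_name: Clinical interpretation of variants in cancer
  accession_pattern: 'civic\.vid:\d+'
  example_accession: 'civic.vid:12'
- resource_id: clingen
  display_name: Clinical genome resource
- resource_id: ddbj
  display_name: DNA data bank of Japan
- resource_id: ecocyc
  display_name: EcoCyc
- resource_id: ensembl
  display_name: Ensembl
  accession_pattern: 'ENS[A-Z]{0,4}[FPTG]\d{11}(\.\d+)?'
  example_accession: ENSG00000176261.11
- resource_id: europe_pmc
  display_name: Europe PMC
- resource_id: ena
  display_name: European nucleotide archive
- resource_id: flybase
  display_name: FlyBase
  accession_pattern: 'FB[a-z]{2}\d{7}'
  example_accession: FBgn0003074
- resource_id: gencode
  display_name: GENCODE
- resource_id: gene_ontology
  display_name: Gene ontology
  accession_pattern: 'GO:\d{7}'
  example_accession: 'GO:0005737'
- resource_id: gbif
  display_name: Global biodiversity information facility
- resource_id: gnomad
  display_name: gnomAD
- resource_id: gsa
  display_name: Genome sequence archive
- resource_id: gwas_catalog
  display_name: GWAS catalog
  accession_pattern: 'GCST\d{6,}'
  example_accession: GCST90017001
- resource_id: gxd
  display_name: GXD
- resource_id: hgnc
  display_name: HUGO gene nomenclature committee
- resource_id: disease_ontology
  display_name: Human disease ontology knowledgebase
- resource_id: human_protein_atlas
  display_name: Human protein atlas
  # Human Protein Atlas entries are addressed by Ensembl gene identifiers.
  accession_pattern: 'ENSG\d{11}'
  example_accession: ENSG00000122862
- resource_id: imex
  display_name: IMEx
  accession_pattern: 'IM-\d+(-\d+)?'
  example_accession: IM-23017
- resource_id: interpro
  display_name: InterPro
  accession_pattern: 'IPR\d{6}'
  example_accession: IPR013770
- resource_id: iuphar
  display_name: IUPHAR/BPS Guide to PHARMACOLOGY
- resource_id: lipid_maps
  display_name: LIPID MAPS
  accession_pattern: 'LM(FA|GL|GP|SP|ST|PR|SL|PK)\d{4}([A-Z0-9]{4,6})?'
  example_accession: LMFA01010001
- resource_id: lpsn
  display_name: List of Prokaryotic names with standing in nomenclature
- resource_id: mgd
  display_name: Mouse Genome Database
- resource_id: orphadata
  display_name: Orphadata Science
- resource_id: panther
  display_name: PANTHER
  accession_pattern: 'PTHR\d{5}(:SF\d+)?'
  example_accession: PTHR12345
- resource_id: pharmgkb
  display_name: Pharmacogenomics knowledgebase
  accession_pattern: 'PA\d+'
  example_accession: PA444801
- resource_id: planteome
  display_name: Planteome
- resource_id: pombase
  display_name: PomBase
  # conservative equivalent of the very general public pattern; matches
  # systematic identifiers such as SPAC1142.01.
  accession_pattern: 'SP[A-Z0-9]{2,}\.[0-9]{2}c?'
  example_accession: SPAC1142.01
- resource_id: pdb
  display_name: Protein data bank
  accession_pattern: '[0-9][A-Z0-9]{3}'
  example_accession: 4HHB
- resource_id: proteomexchange
  display_name: ProteomeXchange consortium
  accession_pattern: 'R?PXD\d{6}'
  example_accession: PXD000001
- resource_id: rgd
  display_name: Rat genome database
  # public LUI is a bare digit run; conservative equivalent embeds the
  # namespace prefix (printed exemplars carry it, e.g. "RGD: 69310").
  accession_pattern: 'RGD:\d{4,}'
  example_accession: 'RGD:69310'
- resource_id: reactome
  display_name: Reactome
  accession_pattern: 'R-[A-Z]{3}-\d+(-\d+)?(\.\d+)?'
  example_accession: R-HSA-2168880
- resource_id: rhea
  display_name: Rhea
  # public LUI is a bare five-digit run; conservative equivalent embeds the
  # namespace prefix.
  accession_pattern: 'RHEA:\d{5}'
  example_accession: 'RHEA:12345'
- resource_id: sgd
  display_name: Saccharomyces genome database
  accession_pattern: 'S\d{9}'
  example_accession: S000003707
- resource_id: silva
  display_name: SILVA
  name_excluded: yes
  name_exclusion_reason: confused with first names or surnames
- resource_id: string
  display_name: STRING
  # conservative equivalent of the very general public pattern; matches
  # taxon-qualified protein identifiers such as 9606.ENSP00000354587.
  accession_pattern: '\d+\.ENS[A-Z]{0,4}P\d+'
  example_accession: 10090.ENSMUSP00000000001
  name_excluded: yes
  name_exclusion_reason: confused with the common noun "string"
- resource_id: ucsc
  display_name: UCSC genome browser
- resource_id: uniprot
  display_name: UniProt
  accession_pattern: '[OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2}'
  example_accession: Q8VRN4
  prefix_required: yes
  prefix_tokens:
  - uniprot
- resource_id: veupathdb
  display_name: VEuPathDB
- resource_id: wormbase
  display_name: WormBase
  accession_pattern: 'WB[A-Z][a-z]+\d+'
  example_accession: WBGene00000898
- resource_id: zfin
  display_name: Zebrafish information network
  accession_pattern: 'ZDB-[A-Z]+-\d{6}-\d+'
  example_accession: ZDB-GENE-030820-3
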