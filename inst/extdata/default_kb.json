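{
  "drugs": [
    {"name": "dabrafenib", "class": "small_molecule", "targets": ["BRAF"],
     "synergy_partner": {"drug": "trametinib", "gene": "BRAF"}},
    {"name": "trametinib", "class": "small_molecule", "targets": ["BRAF", "KRAS", "NRAS"],
     "synergy_partner": {"drug": "dabrafenib", "gene": "BRAF"}},
    {"name": "pertuzumab", "class": "monoclonal_antibody", "targets": ["ERBB2"],
     "synergy_partner": {"drug": "trastuzumab", "gene": "ERBB2"}},
    {"name": "trastuzumab", "class": "monoclonal_antibody", "targets": ["ERBB2"],
     "synergy_partner": {"drug": "pertuzumab", "gene": "ERBB2"}},
    {"name": "letrozole", "class": "hormone_modulator", "targets": ["ER"]},
    {"name": "enzalutamide", "class": "hormone_modulator", "targets": ["AR"]},
    {"name": "bevacizumab", "class": "monoclonal_antibody", "targets": ["VEGFA"],
     "anti_vegf": true},
    {"name": "pazopanib", "class": "small_molecule",
     "targets": ["KDR", "FLT1", "FLT4", "KIT", "PDGFRA"], "anti_vegf": true},
    {"name": "olaparib", "class": "parp_inhibitor", "targets": []},
    {"name": "carboplatin", "class": "platinum", "targets": []},
    {"name": "cisplatin", "class": "platinum", "targets": []},
    {"name": "pembrolizumab", "class": "checkpoint_inhibitor", "targets": []},
    {"name": "nivolumab", "class": "checkpoint_inhibitor", "targets": []},
    {"name": "imatinib", "class": "small_molecule", "targets": ["KIT", "PDGFRA", "ABL1"]},
    {"name": "erlotinib", "class": "small_molecule", "targets": ["EGFR"]},
    {"name": "everolimus", "class": "small_molecule", "targets": ["MTOR", "PIK3CA", "PTEN", "STK11", "TSC1"]},
    {"name": "palbociclib", "class": "small_molecule", "targets": ["CDK4", "CDK6", "CDKN2A", "CCND1"]},
    {"name": "gemcitabine", "class": "cytotoxic_other", "targets": []},
    {"name": "paclitaxel", "class": "cytotoxic_other", "targets": []}
  ],
  "brca_related_genes": ["BRCA1", "BRCA2", "PALB2", "ATM", "BARD1", "BRIP1", "RAD51C", "RAD51D"],
  "tp53_vegf_rule_enabled": true,
  "aliases": {
    "herceptin": "trastuzumab",
    "avastin": "bevacizumab",
    "keytruda": "pembrolizumab",
    "opdivo": "nivolumab",
    "gleevec": "imatinib"
  }
}
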