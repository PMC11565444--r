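{
  "schema_name": "colorectal_rcpath",
  "schema_version": "1.0",
  "description": "Controlled vocabulary for the RCPath colorectal cancer dataset fields. Field order is the proforma order. Aliases listed here are curated surface forms; systematic TNM variants (p-prefix stripping, case folds) are generated at load time.",
  "fields": [
    {
      "name": "specimen_type",
      "label": "Specimen type",
      "query_key": "Specimen Type",
      "kind": "categorical",
      "values": ["Total colectomy", "Subtotal colectomy", "Right hemicolectomy",
                 "Transverse colectomy", "Left hemicolectomy", "Sigmoid colectomy",
                 "Hartmann's procedure", "Anterior resection",
                 "Abdominoperineal excision", "Other", "NA"],
      "na_sentinel": "NA",
      "aliases": {
        "hartmanns procedure": "Hartmann's procedure",
        "hartmann procedure": "Hartmann's procedure",
        "hartmann's": "Hartmann's procedure",
        "abdominoperineal resection": "Abdominoperineal excision",
        "abdomino-perineal excision": "Abdominoperineal excision",
        "aper": "Abdominoperineal excision",
        "low anterior resection": "Anterior resection",
        "high anterior resection": "Anterior resection",
        "right colectomy": "Right hemicolectomy",
        "left colectomy": "Left hemicolectomy",
        "extended right hemicolectomy": "Right hemicolectomy",
        "sigmoidectomy": "Sigmoid colectomy",
        "total colectomy with ileorectal anastomosis": "Total colectomy",
        "panproctocolectomy": "Total colectomy"
      },
      "broad_map": {}
    },
    {
      "name": "tumour_type",
      "label": "Tumour type",
      "query_key": "Tumour Type",
      "kind": "categorical",
      "values": ["Adenocarcinoma", "Mucinous adenocarcinoma", "NA"],
      "na_sentinel": "NA",
      "aliases": {
        "adenocarcinoma nos": "Adenocarcinoma",
        "invasive adenocarcinoma": "Adenocarcinoma",
        "moderately differentiated adenocarcinoma": "Adenocarcinoma",
        "mucinous carcinoma": "Mucinous adenocarcinoma",
        "mucin-producing adenocarcinoma": "Mucinous adenocarcinoma",
        "colloid carcinoma": "Mucinous adenocarcinoma"
      },
      "broad_map": {}
    },
    {
      "name": "tumour_site",
      "label": "Tumour site",
      "query_key": "Tumour Site",
      "kind": "categorical",
      "values": ["Caecum", "Ascending colon", "Hepatic flexure", "Transverse colon",
                 "Splenic flexure", "Descending colon", "Sigmoid colon",
                 "Rectosigmoid", "Rectum", "NA"],
      "na_sentinel": "NA",
      "aliases": {
        "cecum": "Caecum",
        "caecal": "Caecum",
        "right flexure": "Hepatic flexure",
        "right colic flexure": "Hepatic flexure",
        "left flexure": "Splenic flexure",
        "left colic flexure": "Splenic flexure",
        "sigmoid": "Sigmoid colon",
        "rectosigmoid junction": "Rectosigmoid",
        "recto-sigmoid": "Rectosigmoid",
        "rectal": "Rectum"
      },
      "broad_map": {}
    },
    {
      "name": "maximum_diameter",
      "label": "Maximum diameter",
      "query_key": "Maximum Diameter",
      "kind": "numeric",
      "numeric_range": [0, 160],
      "unit": "mm",
      "na_sentinel": "NA",
      "aliases": {},
      "broad_map": {}
    },
    {
      "name": "local_invasion",
      "label": "Local invasion",
      "query_key": "Local Invasion",
      "kind": "categorical",
      "values": ["pTIS", "pT0", "pT1", "pT2", "pT3", "pT4", "pT4a", "pT4b", "pTX"],
      "na_sentinel": "pTX",
      "aliases": {
        "ptis": "pTIS",
        "tis": "pTIS",
        "carcinoma in situ": "pTIS",
        "t4a": "pT4a",
        "t4b": "pT4b"
      },
      "broad_map": {"pT4a": "pT4", "pT4b": "pT4"}
    },
    {
      "name": "histologic_grade",
      "label": "Histologic grade",
      "query_key": "Histologic Grade",
      "kind": "categorical",
      "values": ["High", "Low", "NA"],
      "na_sentinel": "NA",
      "aliases": {
        "high grade": "High",
        "low grade": "Low",
        "poorly differentiated": "High",
        "undifferentiated": "High",
        "well differentiated": "Low",
        "moderately differentiated": "Low",
        "g1": "Low",
        "g2": "Low",
        "g3": "High",
        "g4": "High"
      },
      "broad_map": {}
    },
    {
      "name": "examined_nodes",
      "label": "Examined nodes",
      "query_key": "Examined Nodes",
      "kind": "numeric",
      "numeric_range": [0, 116],
      "unit": "count",
      "na_sentinel": "NA",
      "aliases": {},
      "broad_map": {}
    },
    {
      "name": "metastatic_nodes",
      "label": "Metastatic nodes",
      "query_key": "Metastatic Nodes",
      "kind": "numeric",
      "numeric_range": [0, 50],
      "unit": "count",
      "na_sentinel": "NA",
      "aliases": {},
      "broad_map": {}
    },
    {
      "name": "lymph_node_status",
      "label": "Lymph node status",
      "query_key": "Lymph Node Status",
      "kind": "categorical",
      "values": ["pN0", "pN1", "pN1a", "pN1b", "pN1c", "pN2", "pN2a", "pN2b", "pNX"],
      "na_sentinel": "pNX",
      "aliases": {
        "node negative": "pN0",
        "no nodal metastasis": "pN0"
      },
      "broad_map": {"pN1a": "pN1", "pN1b": "pN1", "pN1c": "pN1",
                    "pN2a": "pN2", "pN2b": "pN2"}
    },
    {
      "name": "distant_metastasis",
      "label": "Distant metastatic disease",
      "query_key": "Distant Metastatic Disease",
      "kind": "categorical",
      "values": ["pM0", "pM1", "pM1a", "pM1b", "pM1c", "pMX"],
      "na_sentinel": "pMX",
      "aliases": {
        "no distant metastasis": "pM0",
        "distant metastasis present": "pM1"
      },
      "broad_map": {"pM1a": "pM1", "pM1b": "pM1", "pM1c": "pM1"}
    },
    {
      "name": "resection",
      "label": "Resection",
      "query_key": "Resection",
      "kind": "categorical",
      "values": ["R0", "R1", "R2", "RX"],
      "na_sentinel": "RX",
      "aliases": {
        "complete resection": "R0",
        "clear margins": "R0",
        "microscopic residual": "R1",
        "macroscopic residual": "R2"
      },
      "broad_map": {}
    }
  ]
}
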