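{
  "specimen_type": {
    "category_notes": {
      "Right hemicolectomy": "Removal of the caecum, ascending colon and hepatic flexure",
      "Left hemicolectomy": "Removal of the splenic flexure and descending colon",
      "Hartmann's procedure": "Sigmoid/rectal resection with end colostomy, no anastomosis",
      "Anterior resection": "Resection of the rectum with colorectal anastomosis",
      "Abdominoperineal excision": "Removal of the rectum and anus with permanent colostomy; also written 'APER'",
      "Other": "Any documented resection procedure not in this list"
    },
    "examples": [
      {"report": "Specimen: right hemicolectomy including terminal ileum.", "value": "Right hemicolectomy"},
      {"report": "Operation performed: Hartmanns procedure.", "value": "Hartmann's procedure"}
    ]
  },
  "tumour_type": {
    "category_notes": {
      "Adenocarcinoma": "Conventional gland-forming adenocarcinoma (adenocarcinoma NOS)",
      "Mucinous adenocarcinoma": "More than 50% of the tumour composed of extracellular mucin; also called mucinous or colloid carcinoma"
    },
    "examples": [
      {"report": "Sections show a moderately differentiated adenocarcinoma.", "value": "Adenocarcinoma"},
      {"report": "Tumour is a mucinous carcinoma with abundant mucin lakes.", "value": "Mucinous adenocarcinoma"}
    ]
  },
  "tumour_site": {
    "category_notes": {
      "Caecum": "Also spelled 'cecum'",
      "Hepatic flexure": "Also called the right (colic) flexure",
      "Splenic flexure": "Also called the left (colic) flexure",
      "Rectosigmoid": "Tumour centred at the rectosigmoid junction"
    },
    "examples": [
      {"report": "An ulcerated tumour is present in the sigmoid colon.", "value": "Sigmoid colon"},
      {"report": "Tumour located at the right flexure.", "value": "Hepatic flexure"}
    ]
  },
  "maximum_diameter": {
    "category_notes": {},
    "examples": [
      {"report": "The tumour measures 45 mm in maximum dimension.", "value": "45"},
      {"report": "Tumour size: 3.5 cm.", "value": "35"}
    ]
  },
  "local_invasion": {
    "category_notes": {
      "pTIS": "Carcinoma in situ: intraepithelial or invasion of lamina propria only; also written 'Tis'",
      "pT0": "No evidence of primary tumour",
      "pT1": "Tumour invades the submucosa",
      "pT2": "Tumour invades the muscularis propria",
      "pT3": "Tumour invades through the muscularis propria into pericolorectal tissues",
      "pT4": "Tumour breaches the serosa or invades adjacent structures (broad category when the sub-stage is not given); may also be referred to as 'T4'",
      "pT4a": "Tumour cells breaching the serosa or perforating; may also be referred to as 'T4A', 'pT4', or 'T4'",
      "pT4b": "Tumour directly invades adjacent organs or structures; also written 'T4B'"
    },
    "examples": [
      {"report": "Tumour invades muscularis propria", "value": "pT2"},
      {"report": "Tumour perforates the visceral peritoneum (serosa).", "value": "pT4a"}
    ]
  },
  "histologic_grade": {
    "category_notes": {
      "High": "Poorly differentiated or undifferentiated (G3/G4)",
      "Low": "Well or moderately differentiated (G1/G2)"
    },
    "examples": [
      {"report": "Poorly differentiated adenocarcinoma is seen.", "value": "High"},
      {"report": "The tumour is moderately differentiated.", "value": "Low"}
    ]
  },
  "examined_nodes": {
    "category_notes": {},
    "examples": [
      {"report": "Twenty-two lymph nodes were examined (22).", "value": "22"},
      {"report": "Nodes examined: 14.", "value": "14"}
    ]
  },
  "metastatic_nodes": {
    "category_notes": {},
    "examples": [
      {"report": "3 of 17 lymph nodes contain metastatic carcinoma.", "value": "3"},
      {"report": "All sampled nodes are free of tumour (0/12).", "value": "0"}
    ]
  },
  "lymph_node_status": {
    "category_notes": {
      "pN0": "No regional lymph node metastasis",
      "pN1": "Metastasis in 1-3 regional nodes (broad category); also written 'N1'",
      "pN1a": "Metastasis in 1 regional node",
      "pN1b": "Metastasis in 2-3 regional nodes",
      "pN1c": "Tumour deposits without regional nodal metastasis",
      "pN2": "Metastasis in 4 or more regional nodes (broad category); also written 'N2'",
      "pN2a": "Metastasis in 4-6 regional nodes",
      "pN2b": "Metastasis in 7 or more regional nodes"
    },
    "examples": [
      {"report": "Two of fifteen nodes are involved by tumour (pN1b).", "value": "pN1b"},
      {"report": "0/18 lymph nodes positive.", "value": "pN0"}
    ]
  },
  "distant_metastasis": {
    "category_notes": {
      "pM0": "No distant metastasis identified",
      "pM1": "Distant metastasis present (broad category); also written 'M1'",
      "pM1a": "Metastasis confined to one organ or site",
      "pM1b": "Metastases in more than one organ or site",
      "pM1c": "Metastasis to the peritoneal surface"
    },
    "examples": [
      {"report": "A liver segment biopsy shows metastatic adenocarcinoma (M1a).", "value": "pM1a"},
      {"report": "No evidence of distant metastatic disease.", "value": "pM0"}
    ]
  },
  "resection": {
    "category_notes": {
      "R0": "Complete resection, all margins clear of tumour",
      "R1": "Microscopic residual disease (margin involved microscopically)",
      "R2": "Macroscopic residual disease"
    },
    "examples": [
      {"report": "All resection margins are free of tumour.", "value": "R0"},
      {"report": "Tumour is present at the circumferential margin.", "value": "R1"}
    ]
  }
}
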