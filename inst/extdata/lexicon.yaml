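# Radiology descriptor lexicon for LDCT annotation topic extraction.
# 14 topics: set1 groups descriptors associated with a LOWER likelihood of a
# nodule being malignant, set2 with a HIGHER likelihood. Synonym surface forms
# are stored in normalized (lowercased, lemmatized) form; multi-word phrases
# are matched on the joined normalized text before single tokens. Every
# surface form maps to exactly one topic.
topics:
  solid:
    display: Solid
    synonyms: [solid]
  single:
    display: Single
    synonyms: [single, solitary]
  small:
    display: Small
    synonyms: [small, tiny, "< 5 mm", subcentimeter, minute]
  benign:
    display: Benign
    synonyms: [benign, harmless]
  circumscribed:
    display: Circumscribed
    synonyms: [circumscribed, smooth, "well defined", "well circumscribed"]
  calcification:
    display: Calcified granuloma/calcification
    synonyms: [calcified, calcification, calcific, granuloma, "calcified granuloma"]
  adenocarcinoma:
    display: Adenocarcinoma
    synonyms: [adenocarcinoma]
  malignant:
    display: Malignant
    synonyms: [malignant, malignancy, cancer, carcinoma, suspicious]
  irregular:
    display: Irregular/ill-defined
    synonyms: [irregular, "ill defined", "poorly defined"]
  spiculated:
    display: Satellite/spiculated
    synonyms: [spiculated, spiculation, spicule, satellite]
  consolidation:
    display: Consolidation
    synonyms: [consolidation, consolidative, airspace]
  indeterminate:
    display: Indeterminate
    synonyms: [indeterminate, equivocal, uncertain, unclear]
  lobulated:
    display: Lobulated
    synonyms: [lobulated, lobular, lobulation]
  nonspecific:
    display: Non-specific
    synonyms: [nonspecific, "non specific"]
set1: [solid, single, small, benign, circumscribed, calcification]
set2: [adenocarcinoma, malignant, irregular, spiculated, consolidation,
       indeterminate, lobulated, nonspecific]
# high-level anatomical/pathological labels, in priority order: the first
# label whose keyword set intersects the normalized annotation wins
main_labels:
  nodule: [nodule, mass, lesion]
  vessel: [vessel, vein, artery, vascular, venous, arterial]
  diaphragm_rib: [diaphragm, diaphragmatic, rib, costal, bone]
  opacity: [opacity, opacification, "ground glass", haziness]
  other: [fissure, airway, bronchus, scar, atelectasis, pleura, pleural]
# additional in-dictionary CT reporting terms (kept by the spell corrector,
# carry no topic)
dictionary: [lung, lobe, upper, lower, left, right, apex, apical, chest,
             margin, border, density, nodular, area, region, mm, cm, likely,
             probable, appearance, round, rounded, oval, peripheral, central,
             subpleural, anterior, posterior, ground, glass, ill, defined,
             well, non, specific]
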