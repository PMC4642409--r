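type_name	tree
Event	Event
Activity	Event
Behavior	Event
Social Behavior	Event
Individual Behavior	Event
Daily or Recreational Activity	Event
Occupational Activity	Event
Health Care Activity	Event
Laboratory Procedure	Event
Diagnostic Procedure	Event
Therapeutic or Preventive Procedure	Event
Research Activity	Event
Molecular Biology Research Technique	Event
Governmental or Regulatory Activity	Event
Educational Activity	Event
Machine Activity	Event
Phenomenon or Process	Event
Human-caused Phenomenon or Process	Event
Environmental Effect of Humans	Event
Natural Phenomenon or Process	Event
Biologic Function	Event
Physiologic Function	Event
Organism Function	Event
Mental Process	Event
Organ or Tissue Function	Event
Cell Function	Event
Molecular Function	Event
Genetic Function	Event
Pathologic Function	Event
Mental or Behavioral Dysfunction	Event
Neoplastic Process	Event
Cell or Molecular Dysfunction	Event
Experimental Model of Disease	Event
Injury or Poisoning	Event
Entity	Entity
Physical Object	Entity
Organism	Entity
Bacterium	Entity
Virus	Entity
Fungus	Entity
Plant	Entity
Animal	Entity
Vertebrate	Entity
Mammal	Entity
Human	Entity
Anatomical Structure	Entity
Embryonic Structure	Entity
Fully Formed Anatomical Structure	Entity
Body Part, Organ, or Organ Component	Entity
Tissue	Entity
Cell	Entity
Cell Component	Entity
Gene or Genome	Entity
Body Location or Region	Entity
Body Space or Junction	Entity
Body Substance	Entity
Body System	Entity
Manufactured Object	Entity
Medical Device	Entity
Research Device	Entity
Clinical Drug	Entity
Food	Entity
Chemical	Entity
Chemical Viewed Functionally	Entity
Chemical Viewed Structurally	Entity
Organic Chemical	Entity
Inorganic Chemical	Entity
Element, Ion, or Isotope	Entity
Amino Acid, Peptide, or Protein	Entity
Nucleic Acid, Nucleoside, or Nucleotide	Entity
Pharmacologic Substance	Entity
Antibiotic	Entity
Biomedical or Dental Material	Entity
Biologically Active Substance	Entity
Hormone	Entity
Enzyme	Entity
Vitamin	Entity
Immunologic Factor	Entity
Receptor	Entity
Hazardous or Poisonous Substance	Entity
Conceptual Entity	Entity
Idea or Concept	Entity
Temporal Concept	Entity
Qualitative Concept	Entity
Quantitative Concept	Entity
Spatial Concept	Entity
Functional Concept	Entity
Finding	Entity
Sign or Symptom	Entity
Laboratory or Test Result	Entity
Organism Attribute	Entity
Clinical Attribute	Entity
Intellectual Product	Entity
Classification	Entity
Regulation or Law	Entity
Language	Entity
Occupation or Discipline	Entity
Biomedical Occupation or Discipline	Entity
Organization	Entity
Health Care Related Organization	Entity
Professional or Occupational Group	Entity
Population Group	Entity
Family Group	Entity
Age Group	Entity
Patient or Disabled Group	Entity
Group	Entity
Geographic Area	Entity
Disease or Syndrome	Entity
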