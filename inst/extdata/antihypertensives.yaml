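# Example antihypertensive drug vocabulary.
# A fixture covering the drug classes screened in FAERS antihypertensive
# signal studies, with a few verbatim synonyms (brand names, dose-qualified
# strings) per drug. Not a complete dictionary: real analyses supply their
# own vocabulary in this schema (canonical, class, synonyms[]).
class_order:
  - Diuretics
  - Antihypertensive drugs with central action
  - Alpha blockers
  - Beta blockers
  - Alpha and beta blockers
  - Calcium channel blockers
  - Angiotensin converting enzyme inhibitors
  - Angiotensin II receptor blockers
  - Renin inhibitors
  - Vasodilators
  - Compound preparations
drugs:
  - canonical: furosemide
    class: Diuretics
    synonyms: [Lasix, FUROSEMIDE 40MG]
  - canonical: hydrochlorothiazide
    class: Diuretics
    synonyms: [HCTZ, Microzide]
  - canonical: spironolactone
    class: Diuretics
    synonyms: [Aldactone]
  - canonical: clonidine
    class: Antihypertensive drugs with central action
    synonyms: [Catapres]
  - canonical: doxazosin
    class: Alpha blockers
    synonyms: [Cardura]
  - canonical: terazosin
    class: Alpha blockers
    synonyms: [Hytrin]
  - canonical: metoprolol
    class: Beta blockers
    synonyms: [Lopressor, Toprol-XL, METOPROLOL TARTRATE]
  - canonical: atenolol
    class: Beta blockers
    synonyms: [Tenormin]
  - canonical: carvedilol
    class: Alpha and beta blockers
    synonyms: [Coreg]
  - canonical: amlodipine
    class: Calcium channel blockers
    synonyms: [Norvasc, AMLODIPINE BESYLATE]
  - canonical: nifedipine
    class: Calcium channel blockers
    synonyms: [Adalat, Procardia]
  - canonical: diltiazem
    class: Calcium channel blockers
    synonyms: [Cardizem]
  - canonical: lisinopril
    class: Angiotensin converting enzyme inhibitors
    synonyms: [Zestril, Prinivil]
  - canonical: enalapril
    class: Angiotensin converting enzyme inhibitors
    synonyms: [Vasotec]
  - canonical: losartan
    class: Angiotensin II receptor blockers
    synonyms: [Cozaar, LOSARTAN POTASSIUM]
  - canonical: valsartan
    class: Angiotensin II receptor blockers
    synonyms: [Diovan]
  - canonical: aliskiren
    class: Renin inhibitors
    synonyms: [Tekturna]
  - canonical: hydralazine
    class: Vasodilators
    synonyms: [Apresoline]
  - canonical: nitroglycerin
    class: Vasodilators
    synonyms: [Nitrostat, GLYCERYL TRINITRATE]
  - canonical: Hyzaar (losartan potassium and hydrochlorothiazide)
    class: Compound preparations
    synonyms: [Hyzaar]
  - canonical: Diovan HCT (valsartan and hydrochlorothiazide)
    class: Compound preparations
    synonyms: [Diovan HCT]
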