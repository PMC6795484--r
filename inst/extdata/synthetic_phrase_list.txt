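# Synthetic stand-in phrase list for the rule-based overdose classifier.
# One word or bigram per line; matching is on token boundaries against the
# normalized certificate text. Replace with your jurisdiction's curated list.
OVERDOSE
TOXICITY
INTOXICATION
POISONING
HEROIN
FENTANYL
COCAINE
METHAMPHETAMINE
AMPHETAMINE
OXYCODONE
HYDROCODONE
MORPHINE
METHADONE
ALPRAZOLAM
DIAZEPAM
CLONAZEPAM
ETHANOL
OPIOID
OPIATE
BUPRENORPHINE
GABAPENTIN
TRAMADOL
DRUG OVERDOSE
MIXED DRUG
DRUG TOXICITY
DRUG INTOXICATION
SUBSTANCE ABUSE
DRUG ABUSE
POLYSUBSTANCE ABUSE
ACCIDENTAL OVERDOSE
DRUG INGESTION
MULTIPLE DRUG
COMBINED DRUG
ACUTE INTOXICATION
POLYDRUG TOXICITY
ILLICIT DRUG
DRUG POISONING
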