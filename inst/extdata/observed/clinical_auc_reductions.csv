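victim,pct_reduction,citation
midazolam,94.7,"Backman 1996 Clin Pharmacol Ther 59:7 (rifampicin 600 mg x5)"
alfentanil,94.5,"Kharasch 2004 Clin Pharmacol Ther 76:452 (oral alfentanil)"
atorvastatin,80.2,"Backman 2005 Clin Pharmacol Ther 78:154"
omeprazole,86.1,"Yucel 2008 Eur J Clin Pharmacol (rifampicin 450 mg x6)"
pioglitazone,56.3,"Jaakkola 2006 Br J Clin Pharmacol 61:70"
tolbutamide,63.5,"Zilly 1975/1977 Eur J Clin Pharmacol (rifampicin 600 mg x14)"
glyburide,38.9,"Niemi 2001 Clin Pharmacol Ther 69:400"
bupropion,67.2,"Loboz 2006 Clin Pharmacol Ther 80:75"
repaglinide,57.5,"Niemi 2000/Hatorp 2003 (rifampicin 600 mg)"
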