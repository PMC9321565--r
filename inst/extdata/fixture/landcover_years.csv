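year,file
2001,landcover_2001.asc
2002,landcover_2002.asc
2003,landcover_2003.asc
2004,landcover_2004.asc
2005,landcover_2005.asc
2006,landcover_2006.asc
2007,landcover_2007.asc
2008,landcover_2008.asc
2009,landcover_2009.asc
2010,landcover_2010.asc
2011,landcover_2011.asc
2012,landcover_2012.asc
2013,landcover_2013.asc
2014,landcover_2014.asc
2015,landcover_2015.asc
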