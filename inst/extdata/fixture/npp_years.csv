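year,file
2001,npp_2001.asc
2002,npp_2002.asc
2003,npp_2003.asc
2004,npp_2004.asc
2005,npp_2005.asc
2006,npp_2006.asc
2007,npp_2007.asc
2008,npp_2008.asc
2009,npp_2009.asc
2010,npp_2010.asc
2011,npp_2011.asc
2012,npp_2012.asc
2013,npp_2013.asc
2014,npp_2014.asc
2015,npp_2015.asc
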