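# Name pools and the phonetic-variant table used by the synthetic generator.
# The common-surname pool deliberately contains short (<= 4 letter) surnames:
# a single discrepancy in a two- or three-letter string carries a large
# negative agreement weight, the known failure mode for very common short
# surnames in registry linkage.

.pool_surnames_common <- c(
  "LEE", "LI", "KIM", "NG", "CHAN", "CHEN", "WONG", "WANG", "LIU", "LAM",
  "LIN", "YANG", "ZHU", "XU", "HO", "CHO", "PARK", "SHAH", "KHAN", "RAO"
)

.pool_surnames_main <- c(
  "SMITH", "BROWN", "TREMBLAY", "MARTIN", "ROY", "WILSON", "MACDONALD",
  "GAGNON", "JOHNSON", "TAYLOR", "CAMPBELL", "ANDERSON", "JONES", "LEBLANC",
  "COTE", "WILLIAMS", "MILLER", "THOMPSON", "GAUTHIER", "WHITE", "MORIN",
  "BOUCHARD", "JOHNSTON", "LAVOIE", "FORTIN", "SCOTT", "STEWART", "REID",
  "BELANGER", "CLARK", "ROBINSON", "PELLETIER", "LEVESQUE", "WALKER",
  "YOUNG", "GIRARD", "WRIGHT", "ROSS", "MITCHELL", "SIMARD", "THOMAS",
  "MOORE", "KING", "BAKER", "HALL", "GREEN", "ADAMS", "NELSON", "HILL",
  "MURPHY", "CAMERON", "GRAHAM", "KENNEDY", "FRASER", "GRANT", "MCLEAN",
  "HAMILTON", "FERGUSON", "MURRAY", "KELLY", "SULLIVAN", "BENNETT", "WOOD",
  "WATSON", "RICHARDSON", "HARRIS", "LEWIS", "COOPER", "BAILEY", "BELL",
  "PATEL", "SINGH", "GILL", "DHILLON", "SIDHU", "GREWAL", "SANDHU", "BRAR",
  "SHARMA", "KUMAR", "GUPTA", "VERMA", "MEHTA", "REDDY", "NAIR", "IYER",
  "FERNANDES", "DSOUZA", "PEREIRA", "SILVA", "SANTOS", "GARCIA", "MARTINEZ",
  "RODRIGUEZ", "LOPEZ", "GONZALEZ", "HERNANDEZ", "PEREZ", "SANCHEZ",
  "RAMIREZ", "TORRES", "FLORES", "RIVERA", "NGUYEN", "TRAN", "PHAM",
  "HOANG", "VU", "DANG", "BUI", "DO", "HUYNH", "TRUONG", "ALI", "AHMED",
  "HASSAN", "HUSSEIN", "IBRAHIM", "MOHAMED", "ABDI", "OMAR", "YUSUF",
  "OSMAN", "KOWALSKI", "NOWAK", "WISNIEWSKI", "WOJCIK", "KAMINSKI",
  "LEWANDOWSKI", "ZIELINSKI", "SZYMANSKI", "MUELLER", "SCHMIDT",
  "SCHNEIDER", "FISCHER", "WEBER", "MEYER", "WAGNER", "BECKER", "SCHULZ",
  "HOFFMANN", "PETERSEN", "HANSEN", "JENSEN", "NIELSEN", "ANDERSEN",
  "JOHANSSON", "ERIKSSON", "LINDBERG", "ROSSI", "RUSSO", "FERRARI",
  "ESPOSITO", "BIANCHI", "ROMANO", "COLOMBO", "RICCI", "GREENE", "CLARKE",
  "PEARSON", "PIERSON", "BAUMANN", "BOWMAN", "MEIER", "MAIER", "STUART",
  "NEILSON", "NIELSON", "THOMSON", "TOMSON", "HANSON", "JANSEN", "YEE",
  "YI", "LEW", "SCHWARTZ", "SWARTZ", "MACLEAN", "READ", "REED", "WILLSON",
  "OLSEN", "OLSON", "OLSSON", "KAUR", "CARR", "KERR", "WOODS", "DEAN",
  "DEEN", "MCDONALD", "BRAUN", "BROWNE", "MULLER", "JOHNSEN", "MAYER",
  "KOHN", "COEN"
)

.pool_given_f <- c(
  "MARY", "LINDA", "SUSAN", "MARGARET", "PATRICIA", "CAROL", "NANCY",
  "ELIZABETH", "BARBARA", "DONNA", "KAREN", "SANDRA", "HELEN", "DIANE",
  "SHARON", "JENNIFER", "MICHELLE", "LISA", "KELLY", "AMANDA", "SARAH",
  "JESSICA", "ASHLEY", "EMILY", "SAMANTHA", "STEPHANIE", "NICOLE",
  "MELISSA", "REBECCA", "LAURA", "AMY", "ANNA", "MARIA", "WEI", "MEI",
  "YAN", "LING", "XIA", "HUI", "FATIMA", "AISHA", "AMINA", "ZAINAB",
  "PRIYA", "ANITA", "SUNITA", "KAVITA", "DEEPA", "LAKSHMI", "ROSA",
  "CARMEN", "ELENA", "SOFIA", "ISABEL", "INGRID", "ASTRID", "EVA",
  "OLGA", "IRINA", "NATASHA"
)

.pool_given_m <- c(
  "JAMES", "JOHN", "ROBERT", "MICHAEL", "WILLIAM", "DAVID", "RICHARD",
  "JOSEPH", "DONALD", "GEORGE", "KENNETH", "STEVEN", "EDWARD", "BRIAN",
  "RONALD", "ANTHONY", "KEVIN", "JASON", "MATTHEW", "GARY", "TIMOTHY",
  "JOSE", "LARRY", "JEFFREY", "FRANK", "SCOTT", "ERIC", "STEPHEN",
  "ANDREW", "RAYMOND", "GREGORY", "JOSHUA", "JERRY", "DENNIS", "WALTER",
  "PATRICK", "PETER", "HAROLD", "DOUGLAS", "HENRY", "CARL", "ARTHUR",
  "RYAN", "WEI", "JUN", "MING", "HAO", "CHEN", "MOHAMMED", "AHMED",
  "ALI", "OMAR", "HASSAN", "RAJ", "AMIT", "SANJAY", "VIJAY", "RAHUL",
  "CARLOS", "JUAN", "LUIS", "MIGUEL", "ANTONIO", "IVAN", "DMITRI",
  "SERGEI", "ANDREI", "LARS", "ERIK", "HANS"
)

# Classes of same-NYSIIS spelling variants; every member of a class carries
# the same phonetic code (asserted by the test suite), so a swap within a
# class survives NYSIIS blocking while breaking exact comparison.
.phonetic_variant_classes <- list(
  c("BROWN", "BRAUN", "BROWNE"),
  c("MACDONALD", "MCDONALD"),
  c("GREEN", "GREENE"),
  c("MUELLER", "MULLER"),
  c("PEARSON", "PIERSON"),
  c("BAUMANN", "BOWMAN"),
  c("CLARK", "CLARKE"),
  c("MEIER", "MAIER"),
  c("MEYER", "MAYER"),
  c("STEWART", "STUART"),
  c("KOHN", "COEN"),
  c("NEILSON", "NIELSEN", "NELSON", "NIELSON"),
  c("THOMSON", "TOMSON"),
  c("HANSEN", "HANSON"),
  c("JENSEN", "JANSEN"),
  c("JOHNSON", "JOHNSEN"),
  c("WONG", "WANG"),
  c("YEE", "YI"),
  c("LI", "LIU", "LEW"),
  c("SCHWARTZ", "SWARTZ"),
  c("ANDERSEN", "ANDERSON"),
  c("MACLEAN", "MCLEAN"),
  c("REID", "READ", "REED"),
  c("WILSON", "WILLSON"),
  c("PETERSEN", "PETERSON"),
  c("OLSEN", "OLSON", "OLSSON"),
  c("KAUR", "CARR", "KERR"),
  c("WOOD", "WOODS"),
  c("DEAN", "DEEN")
)

#' The shipped table of same-NYSIIS surname variants
#'
#' Each list element is a class of spellings sharing one NYSIIS code; the
#' phonetic-swap corruption operator substitutes within a class.
#'
#' @return list of character vectors.
#' @export
phonetic_variant_table <- function() .phonetic_variant_classes

.postal_fsa <- c("M4N", "M5G", "M1B", "K1Y", "K2P", "L5B", "L8S", "N2L",
                 "N6A", "P3E", "P7B", "K7L")

.immigrant_classes <- c("Family Class", "Economic Immigrants",
                        "Refugees/Asylum Seekers", "Other")
.regions_of_birth <- c("Eastern Asia", "Southern Asia", "South East Asia",
                       "Eastern Europe", "Western Europe", "Caribbean/Bermuda",
                       "South America", "Eastern Africa", "Northern Africa",
                       "North America")
.death_causes <- c("Neoplasms", "Circulatory", "Respiratory", "External",
                   "Perinatal", "Congenital", "Endocrine", "Infectious",
                   "Mental", "Other")
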